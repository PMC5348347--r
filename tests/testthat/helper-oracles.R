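# Independent brute-force oracles used across the suite. These share no
# code with the package implementation.

# per-basepair membership on a toy genome: interval set -> logical vector
# per chromosome
bp_membership <- function(intervals, chrom_lengths) {
  out <- lapply(names(chrom_lengths), function(ch) {
    v <- logical(chrom_lengths[[ch]])
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(iv))) {
      v[(iv$start[i] + 1):iv$end[i]] <- TRUE # 0-based half-open -> 1-based
    }
    v
  })
  names(out) <- names(chrom_lengths)
  out
}

membership_to_intervals <- function(memb) {
  out <- NULL
  for (ch in names(memb)) {
    v <- memb[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep)) {
      out <- rbind(out, data.frame(chrom = ch, start = starts[keep] - 1,
                                   end = ends[keep],
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

random_intervals <- function(n, chrom_lengths) {
  chs <- sample(names(chrom_lengths), n, replace = TRUE)
  s <- vapply(chs, function(ch) sample.int(chrom_lengths[[ch]] - 1, 1),
              numeric(1))
  len <- vapply(chs, function(ch) sample.int(chrom_lengths[[ch]] / 4, 1),
                numeric(1))
  e <- pmin(s + len, vapply(chs, function(ch) chrom_lengths[[ch]],
                            numeric(1)))
  data.frame(chrom = chs, start = s, end = e, stringsAsFactors = FALSE)
}

# exhaustive minimizer of sum((x - segment mean)^2) + penalty * breaks
# over all 2^(n-1) breakpoint sets
exhaustive_segmentation_cost <- function(value, penalty) {
  n <- length(value)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    breaks <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, breaks, n)
    cost <- penalty * length(breaks)
    for (k in seq_len(length(bounds) - 1)) {
      seg <- value[(bounds[k] + 1):bounds[k + 1]]
      cost <- cost + sum((seg - mean(seg))^2)
    }
    if (cost < best) best <- cost
  }
  best
}

dp_solution_cost <- function(segs, value, pos, penalty) {
  cost <- penalty * (nrow(segs) - 1)
  for (i in seq_len(nrow(segs))) {
    seg <- value[pos >= segs$start[i] & pos < segs$end[i]]
    cost <- cost + sum((seg - mean(seg))^2)
  }
  cost
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
exact_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- u_stat(x, y)
  m <- length(pooled)
  combs <- utils::combn(m, n)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mu <- n * (m - n) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# step-by-step random-effects chain in plain arithmetic (no shared code)
brute_meta_chain <- function(n1, n2, m1, m2, s1, s2) {
  k <- length(n1)
  g <- numeric(k); v <- numeric(k)
  for (i in 1:k) {
    sp <- sqrt(((n1[i] - 1) * s1[i]^2 + (n2[i] - 1) * s2[i]^2) /
                 (n1[i] + n2[i] - 2))
    d <- (m2[i] - m1[i]) / sp
    J <- 1 - 3 / (4 * (n1[i] + n2[i] - 2) - 1)
    g[i] <- J * d
    v[i] <- (n1[i] + n2[i]) / (n1[i] * n2[i]) + g[i]^2 / (2 * (n1[i] + n2[i]))
  }
  w <- 1 / v
  gbar <- sum(w * g) / sum(w)
  Q <- sum(w * (g - gbar)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / C)
  ws <- 1 / (v + tau2)
  pooled <- sum(ws * g) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(g = g, v = v, Q = Q, tau2 = tau2, pooled = pooled, se = se,
       I2 = max(0, (Q - (k - 1)) / Q) * 100,
       z = pooled / se)
}

# small paired expression matrix with named columns for a design
paired_matrix <- function(design, n_genes, seed = 1, sd = 1) {
  set.seed(seed)
  cols <- c(rbind(design$pairs$diagnosis, design$pairs$relapse))
  matrix(rnorm(n_genes * length(cols), 0, sd), n_genes, length(cols),
         dimnames = list(sprintf("g%04d", seq_len(n_genes)), cols))
}
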