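# Independent oracles used across the suite. These deliberately use naive
# algorithms (brute force, enumeration, plain Monte Carlo) so they stay
# independent of the implementation paths they check.

# Naive O(n^3) Ward agglomeration: at each step merge the pair of clusters
# whose fusion minimizes the increase in within-cluster sum of squares.
# Returns the sequence of merged member sets (each a sorted index vector).
oracle_ward_merges <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  clusters <- lapply(seq_len(n), function(i) i)
  merges <- list()
  while (length(clusters) > 1) {
    best <- Inf
    bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        a <- clusters[[i]]
        b <- clusters[[j]]
        ma <- colMeans(X[a, , drop = FALSE])
        mb <- colMeans(X[b, , drop = FALSE])
        d <- length(a) * length(b) / (length(a) + length(b)) *
          sum((ma - mb)^2)
        if (d < best) {
          best <- d
          bi <- i
          bj <- j
        }
      }
    }
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    merges[[length(merges) + 1]] <- merged
    clusters[[bi]] <- merged
    clusters[[bj]] <- NULL
  }
  merges
}

# Merge sequence of an hclust tree as member sets.
hclust_merges <- function(hc) {
  n <- length(hc$order)
  sets <- list()
  merges <- list()
  for (s in seq_len(n - 1)) {
    members <- c()
    for (x in hc$merge[s, ]) {
      members <- c(members, if (x < 0) -x else sets[[x]])
    }
    sets[[s]] <- sort(members)
    merges[[s]] <- sets[[s]]
  }
  merges
}

# Exhaustive minimum WCSS over all 2-cluster partitions.
oracle_kmeans2_wcss <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- Inf
  wss <- function(idx) {
    if (length(idx) == 0) return(0)
    M <- X[idx, , drop = FALSE]
    sum(sweep(M, 2, colMeans(M))^2)
  }
  for (code in 1:(2^(n - 1) - 1)) {
    inA <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(n - 2)))))
    best <- min(best, wss(which(inA)) + wss(which(!inA)))
  }
  best
}

# Exhaustive minimum WCSS over contiguous k-partitions of sorted 1-D data.
oracle_contiguous_wcss <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  ss <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    tot <- 0
    for (m in seq_len(k)) tot <- tot + ss(xs[(b[m] + 1):b[m + 1]])
    best <- min(best, tot)
  }
  best
}

# Exact two-sided Mann-Whitney p-value by full enumeration of group
# labellings (no ties assumed).
oracle_mw_exact_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # observed U for x
  mu <- nx * length(y) / 2
  idx <- utils::combn(length(pooled), nx)
  stats <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Reference MCA via vegan's correspondence analysis of the indicator
# matrix: eigenvalues and principal column coordinates (v are standard
# coordinates; principal = v * sqrt(eigenvalue)).
reference_mca <- function(Z) {
  m <- vegan::cca(as.data.frame(Z))
  eig <- unname(m$CA$eig)
  list(eigenvalues = eig,
       modality_coords = m$CA$v %*% diag(sqrt(eig), length(eig)))
}

# Monte-Carlo oracle of the generator's marginal transform for two
# variables sharing the latent factor: reproduces mu + sd * standardized
# (a z + s e), rounding and clipping, independently of generate_cohort().
oracle_transform_spearman <- function(a1, a2, noise_sd, reg1, reg2,
                                      n = 1e6, seed = 424242) {
  set.seed(seed)
  z <- rnorm(n)
  mk <- function(a, reg) {
    s <- (a * z + noise_sd * rnorm(n)) / sqrt(a^2 + noise_sd^2)
    raw <- reg$mu_women + reg$sd_women * s
    pmin(reg$hi, pmax(reg$lo, round(raw / reg$granularity) * reg$granularity))
  }
  cor(mk(a1, reg1), mk(a2, reg2), method = "spearman")
}

# Random small coded table (n subjects, Q variables, 2-4 labels each).
random_coded_table <- function(n, Q, seed) {
  set.seed(seed)
  repeat {
    df <- as.data.frame(lapply(seq_len(Q), function(q) {
      nlev <- sample(2:4, 1)
      sample(paste0("l", seq_len(nlev)), n, replace = TRUE)
    }), col.names = paste0("v", seq_len(Q)), stringsAsFactors = FALSE)
    # ensure no constant variable (would give an empty-modality warning)
    if (all(vapply(df, function(x) length(unique(x)) >= 2, logical(1)))) {
      rownames(df) <- paste0("s", seq_len(n))
      return(df)
    }
  }
}
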