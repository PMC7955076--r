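# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive (explicit loops, textbook formulas) and never call the
# package code paths they check.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# pairwise Pearson across features by explicit double loop
oracle_msn_weights <- function(m) {
  n <- nrow(m)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) w[i, j] <- oracle_pearson(m[i, ], m[j, ])
    }
  }
  w
}

# OLS group t-statistic by normal equations
oracle_ols_t <- function(y, x, coef_idx = 2) {
  xtx <- t(x) %*% x
  beta <- solve(xtx, t(x) %*% y)
  res <- y - x %*% beta
  df <- nrow(x) - ncol(x)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(xtx)[coef_idx, coef_idx])
  list(t = beta[coef_idx] / se, df = df,
       p = 2 * stats::pt(-abs(beta[coef_idx] / se), df))
}

# Benjamini-Hochberg step-up by the definition: q_i = min over tail ranks of
# p_(j) * m / j, clipped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  q
}

# iterative NIPALS first PLS component (univariate response)
oracle_nipals_pls1 <- function(x, y, scale_x = TRUE, tol = 1e-12, maxit = 500) {
  xc <- scale(x, center = TRUE, scale = scale_x)
  yc <- y - mean(y)
  w <- rep(1 / sqrt(ncol(xc)), ncol(xc))
  for (it in seq_len(maxit)) {
    t_ <- xc %*% w
    c_ <- sum(yc * t_) / sum(t_^2)
    u <- yc / c_
    w_new <- as.numeric(crossprod(xc, u))
    w_new <- w_new / sqrt(sum(w_new^2))
    if (sum((w_new - w)^2) < tol) { w <- w_new; break }
    w <- w_new
  }
  w
}

# two-sided Fisher exact p by enumeration over tables with fixed margins
oracle_fisher_p <- function(a, b, c_, d) {
  rm1 <- a + b; rm2 <- c_ + d; cm1 <- a + c_
  n <- rm1 + rm2
  prob <- function(x) {
    choose(rm1, x) * choose(rm2, cm1 - x) / choose(n, cm1)
  }
  xs <- max(0, cm1 - rm2):min(rm1, cm1)
  p_obs <- prob(a)
  sum(vapply(xs, prob, numeric(1))[vapply(xs, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# small standard fixtures -----------------------------------------------

tiny_atlas <- function(n = 12, n_systems = 3) make_atlas(n, n_systems)

tiny_features <- function(n_regions = 6, n_features = 4, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_regions * n_features), n_regions, n_features)
    colnames(m) <- paste0("f", seq_len(n_features))
    dplyr::bind_cols(tibble::tibble(region_id = seq_len(n_regions)),
                     tibble::as_tibble(m))
  })
}

# minimal hand-built expression bundle (2 donors) for step-level tests
tiny_bundle <- function() {
  probes <- tibble::tibble(probe_id = c(101L, 102L, 103L, 104L),
                           gene_symbol = c("g1", "g1", "g2", "g3"))
  mk_donor <- function(d, expr) {
    samples <- tibble::tibble(
      sample_id = paste0("D", d, "_S", seq_len(ncol(expr))),
      donor_id = paste0("donor_", d),
      mni_x = 0, mni_y = 0, mni_z = 0,
      structure_id = seq_len(ncol(expr))
    )
    dimnames(expr) <- list(probes$probe_id, samples$sample_id)
    pac <- matrix(1L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
    list(expression = expr, samples = samples, pacall = pac)
  }
  withr::with_seed(9, {
    e1 <- matrix(rnorm(4 * 6, 8), 4, 6)
    e2 <- matrix(rnorm(4 * 6, 8), 4, 6)
    ref <- matrix(rnorm(3 * 6, 8), 3, 6,
                  dimnames = list(c("g1", "g2", "g3"), 1:6))
    structure(list(
      donors = list(donor_1 = mk_donor(1, e1), donor_2 = mk_donor(2, e2)),
      probes = probes,
      probe_mapping = probes,
      reference = ref,
      radius = 75,
      meta = NULL
    ), class = "expression_bundle")
  })
}
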