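# Shared fixtures, built once per test run.

tiny_config <- function(...) {
  args <- list(n_founders_per_line = 40, n_snps = 300, n_qtl = 60,
               n_generations_pb = 3, n_cb_sires = 20, n_f1_sows = 40,
               offspring_per_sire = 8, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# memoised small dataset used by several files
tiny_data <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- suppressWarnings(suppressMessages(
        simulate_dataset(tiny_config())))
    val
  }
})

tiny_bundles <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- suppressWarnings(suppressMessages(
        prepare_bundles(tiny_data())))
    val
  }
})

# random genotype matrix with ids
rand_geno <- function(n, m, p = NULL, seed = 1, prefix = "s") {
  set.seed(seed)
  p <- p %||% runif(m, 0.1, 0.5)
  g <- vapply(p, function(pp) rbinom(n, 2L, pp), integer(n))
  if (n == 1) g <- matrix(g, 1)
  dimnames(g) <- list(sprintf("%s%03d", prefix, seq_len(n)),
                      sprintf("snp%04d", seq_len(m)))
  storage.mode(g) <- "integer"
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent naive Spearman: Pearson on average ranks
naive_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# QP oracle for the SVR dual: quadprog solves the 2n box form (with a small
# PD ridge, which it needs), seeding a textbook primal active-set
# refinement of the unridged problem, so the reported optimum is exact.
qp_svr_oracle <- function(K, y, C, epsilon) {
  n <- length(y)
  l <- 2L * n
  Q0 <- rbind(cbind(K, -K), cbind(-K, K))
  p <- c(epsilon - y, epsilon + y)
  z <- c(rep(1, n), rep(-1, n))
  A <- cbind(z, diag(l), -diag(l))
  b0 <- c(0, rep(0, l), rep(-C, l))
  qp <- quadprog::solve.QP(Q0 + diag(1e-6, l), -p, A, b0, meq = 1)
  t0 <- pmin(pmax(qp$solution, 0), C)
  tol <- 1e-6 * max(1, C)

  # bound[i] = 0 / C when active, NA when free
  bound <- ifelse(t0 < tol, 0, ifelse(t0 > C - tol, C, NA))
  tt <- t0
  lambda <- 0
  for (it in 1:200) {
    # alpha_i and alpha*_i simultaneously free makes the KKT system exactly
    # singular (their Q columns are negatives); with epsilon > 0 at most one
    # is active at the optimum, so pin the smaller one at zero
    both <- which(is.na(bound[1:n]) & is.na(bound[(n + 1):l]))
    for (i2 in both)
      bound[if (tt[i2] <= tt[i2 + n]) i2 else i2 + n] <- 0
    free <- which(is.na(bound))
    fixed <- which(!is.na(bound))
    if (length(free)) {
      kkt <- rbind(cbind(Q0[free, free, drop = FALSE], z[free]),
                   c(z[free], 0))
      rhs <- c(-p[free] -
                 (if (length(fixed))
                    Q0[free, fixed, drop = FALSE] %*% bound[fixed] else 0),
               -sum(z[fixed] * bound[fixed]))
      sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
      if (is.null(sol)) break
      tt <- replace(rep(0, l), fixed, bound[fixed])
      tt[free] <- sol[seq_along(free)]
      lambda <- sol[length(sol)]
      # clamp the worst bound violator among the free set, if any
      lo <- free[tt[free] < -1e-10]
      hi <- free[tt[free] > C + 1e-10]
      if (length(lo) || length(hi)) {
        viol <- c(-tt[lo], tt[hi] - C)
        worst <- c(lo, hi)[which.max(viol)]
        bound[worst] <- if (worst %in% hi) C else 0
        next
      }
    } else {
      tt <- bound
    }
    # release the worst multiplier violation among bound-active variables
    g <- as.numeric(Q0 %*% tt + p) + lambda * z
    rel0 <- fixed[bound[fixed] == 0 & g[fixed] < -1e-9]
    relC <- fixed[bound[fixed] == C & g[fixed] > 1e-9]
    if (!length(rel0) && !length(relC)) break
    viol <- c(-g[rel0], g[relC])
    bound[c(rel0, relC)[which.max(viol)]] <- NA
  }
  tt <- pmin(pmax(tt, 0), C)
  beta <- tt[1:n] - tt[(n + 1):(2 * n)]
  obj <- 0.5 * as.numeric(t(beta) %*% K %*% beta) - sum(y * beta) +
    epsilon * sum(abs(beta))
  list(beta = beta, objective = obj)
}
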