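# Independent brute-force oracles and fixture builders shared across tests.
# The oracles deliberately avoid the package's own code paths.

# item-by-item scoring oracle: loops over items, applies the key's maps
# directly from its metadata (not through the points matrix)
oracle_score <- function(responses, key) {
  n_lev <- key$scale_max - key$scale_min + 1L
  fwd <- switch(key$points_scheme,
    identity   = function(r) r,
    zero_based = function(r) r - key$scale_min,
    agree2     = function(r) c(0, 0, 1, 2)[r - key$scale_min + 1L],
    agree1     = function(r) c(0, 0, 1, 1)[r - key$scale_min + 1L]
  )
  rev_resp <- function(r) key$scale_min + key$scale_max - r
  out <- numeric(0)
  for (s in names(key$subscales)) {
    tot <- 0
    for (i in key$subscales[[s]]) {
      r <- responses[i]
      if (i %in% key$reverse) r <- rev_resp(r)
      tot <- tot + fwd(r)
    }
    out[s] <- tot
  }
  c(out, total = sum(out))
}

# ordinary least squares by explicit normal equations
oracle_ols <- function(X, y) {
  Xd <- cbind(intercept = 1, X)
  XtX <- t(Xd) %*% Xd
  beta <- solve(XtX, t(Xd) %*% y)
  resid <- y - Xd %*% beta
  df <- nrow(Xd) - ncol(Xd)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  list(beta = drop(beta), se = se, t = drop(tval),
       p = 2 * pt(abs(drop(tval)), df, lower.tail = FALSE), df = df,
       rss = sum(resid^2))
}

# sex-adjusted group F by explicit model comparison (restricted vs full)
oracle_group_f <- function(y, group, sex01) {
  X0 <- cbind(sex01)
  G <- stats::model.matrix(~ 0 + group)[, -1, drop = FALSE]  # drop one level
  X1 <- cbind(sex01, G)
  rss0 <- oracle_ols(X0, y)$rss
  fit1 <- oracle_ols(X1, y)
  df1 <- ncol(G)
  df2 <- length(y) - ncol(X1) - 1
  f <- ((rss0 - fit1$rss) / df1) / (fit1$rss / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

# hand Pearson goodness-of-fit chi-square on two cells
oracle_gof <- function(m, f, share_f) {
  n <- m + f
  e <- c(n * (1 - share_f), n * share_f)
  sum((c(m, f) - e)^2 / e)
}

# two-pass mean/SD standardization oracle
oracle_standardize <- function(x) {
  mu <- sum(x) / length(x)
  s <- sqrt(sum((x - mu)^2) / (length(x) - 1))
  (x - mu) / s
}

# small scored cohort with guaranteed non-empty dominance groups
make_cohort <- function(n = 200, seed = 1, ...) {
  cfg <- simulation_config(n = n, seed = seed, ...)
  generate_cohort(cfg, seed = seed)
}

# hand-built tiny cohort with explicit group labels for contrast oracles
make_group_fixture <- function(n_per = 5, seed = 5) {
  set.seed(seed)
  data.frame(
    id = sprintf("P%02d", seq_len(3 * n_per)),
    group = factor(rep(c("EE-dominant", "balanced", "CE-dominant"), each = n_per),
                   levels = c("EE-dominant", "balanced", "CE-dominant")),
    sex = rep(c("m", "f"), length.out = 3 * n_per),
    y = rnorm(3 * n_per, mean = rep(c(12, 10, 9), each = n_per), sd = 2)
  )
}

# wrap a hand-labeled fixture as an ed_profile-shaped data.frame so the
# inference functions can consume it without recomputing groups
as_fake_profile <- function(fix, instrument = "iri") {
  data.frame(id = fix$id, instrument = instrument,
             z_ce = 0, z_ee = 0, ed = 0, ed_magnitude = 0, group = fix$group)
}
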