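# Shared fixtures and independent oracles, built in code at test time.

# memoised small cohort used across test files
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(synth_config(n_patients = 150, seed = 3))
    }
    cache
  }
})

# brute-force AUC: mean concordance over all case-control pairs, ties half
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# independent iteratively-reweighted-least-squares logistic solver
irls_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X1, w * X1), crossprod(X1, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.vector(beta)
}

# responses data frame with all symptom columns set from a named list
toy_responses <- function(n, set = list()) {
  df <- data.frame(response_id = sprintf("R%03d", seq_len(n)),
                   patient_id = sprintf("P%03d", seq_len(n)),
                   postop_day = rep(5L, n))
  for (item in prom_items()) df[[item]] <- rep(0L, n)
  for (nm in names(set)) df[[nm]] <- set[[nm]]
  df$triage_label <- "low"
  df$ssi48 <- 0L
  df
}
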