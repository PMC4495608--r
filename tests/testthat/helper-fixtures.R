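# shared fixtures, built once per test run
fx <- new.env()

fx_montage <- function() {
  if (is.null(fx$montage)) fx$montage <- macaque33_montage()
  fx$montage
}

fx_head <- function() {
  if (is.null(fx$head)) fx$head <- head_model()
  fx$head
}

fx_script <- function(kind = "median") {
  key <- paste0("script_", kind)
  if (is.null(fx[[key]]))
    fx[[key]] <- make_default_script(kind, fx_montage(), fx_head())
  fx[[key]]
}

# random zero-mean scalp map on n channels
random_map <- function(n = 33) {
  v <- stats::rnorm(n)
  v - mean(v)
}

# naive frame-loop GEV used as an independent oracle in several tests
naive_gev <- function(X, templates, labels) {
  n <- nrow(X)
  g <- apply(X, 2, function(v) sqrt(mean((v - mean(v))^2)))
  num <- numeric(ncol(templates))
  for (t in seq_len(ncol(X))) {
    if (is.na(labels[t])) next
    u <- X[, t]; v <- templates[, labels[t]]
    sc <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
    num[labels[t]] <- num[labels[t]] + (g[t] * sc)^2
  }
  per <- num / sum(g^2)
  list(per_map = per, total = sum(per))
}

# match recovered templates to planted ones by best |SC|, requiring a
# one-to-one assignment; returns the matched |SC| values
match_templates <- function(recovered, planted) {
  stopifnot(ncol(recovered) == ncol(planted))
  K <- ncol(planted)
  M <- abs(crossprod(recovered, planted)) /
    outer(sqrt(colSums(recovered^2)), sqrt(colSums(planted^2)))
  perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == K), ,
                 drop = FALSE]
  scores <- apply(perms, 1, function(p) sum(M[cbind(seq_len(K), p)]))
  best <- perms[which.max(scores), ]
  M[cbind(seq_len(K), best)]
}
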