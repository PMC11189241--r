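# Independent oracles, kept deliberately naive and separate from the
# package's implementation paths.

# time-domain HRV by direct formula over a valid-NN list
hrv_oracle <- function(nn, nn_diffs) {
  mean_nn <- sum(nn) / length(nn)
  sdnn <- sqrt(sum((nn - mean_nn)^2) / length(nn))
  rmssd <- if (length(nn_diffs)) sqrt(sum(nn_diffs^2) / length(nn_diffs)) else NA_real_
  c(mean_nn = mean_nn, hr = 60000 / mean_nn, sdnn = sdnn, rmssd = rmssd,
    cvsd = rmssd / mean_nn, cvnn = sdnn / mean_nn)
}

# haversine with the sphere radius used by geosphere (closed form)
haversine_oracle <- function(lat1, lon1, lat2, lon2, r = 6378137) {
  to <- pi / 180
  a <- sin((lat2 - lat1) * to / 2)^2 +
    cos(lat1 * to) * cos(lat2 * to) * sin((lon2 - lon1) * to / 2)^2
  2 * r * asin(sqrt(pmin(1, a)))
}

# path-dependent conditional expectation of one extracted tree
shap_expvalue <- function(tr, x, S, node = 1) {
  if (tr$left[node] == -1) return(tr$value[node])
  f <- tr$feature[node] + 1
  l <- tr$left[node] + 1
  r <- tr$right[node] + 1
  if (f %in% S) {
    if (x[f] <= tr$threshold[node]) shap_expvalue(tr, x, S, l)
    else shap_expvalue(tr, x, S, r)
  } else {
    (tr$cover[l] * shap_expvalue(tr, x, S, l) +
       tr$cover[r] * shap_expvalue(tr, x, S, r)) / tr$cover[node]
  }
}

# exhaustive Shapley values over all 2^M feature subsets for a forest in
# forest_structure() form, averaged over trees
brute_force_shap <- function(forest, x) {
  M <- length(x)
  phi <- numeric(M)
  subsets <- lapply(0:(2^M - 1), function(b) which(bitwAnd(b, 2^(0:(M - 1))) > 0))
  keys <- vapply(subsets, paste, "", collapse = ",")
  for (tr in forest) {
    fx <- vapply(subsets, function(S) shap_expvalue(tr, x, S), numeric(1))
    names(fx) <- keys
    for (i in seq_len(M)) {
      for (si in seq_along(subsets)) {
        S <- subsets[[si]]
        if (i %in% S) next
        w <- factorial(length(S)) * factorial(M - length(S) - 1) / factorial(M)
        phi[i] <- phi[i] +
          w * (fx[[paste(sort(c(S, i)), collapse = ",")]] - fx[[si]])
      }
    }
  }
  phi / length(forest)
}
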