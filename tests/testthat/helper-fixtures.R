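# shared fixtures and independent oracles

# closed-form time to grow d0 -> d1 under each analytically solvable law
closed_form_age <- function(model, p, d0, d1) {
  switch(model,
    mean = (d1 - d0) / p[["c"]],
    linear = log((p[["a"]] + p[["b"]] * d1) /
                 (p[["a"]] + p[["b"]] * d0)) / p[["b"]],
    power = (d1^(1 - p[["b"]]) - d0^(1 - p[["b"]])) /
            (p[["a"]] * (1 - p[["b"]])),
    verhulst = log((d1 / (p[["K"]] - d1)) * ((p[["K"]] - d0) / d0)) /
               p[["r"]],
    gompertz = log(log(p[["K"]] / d0) / log(p[["K"]] / d1)) / p[["a"]])
}

# naive average-linkage agglomeration: returns the 2-cluster partition as a
# list of sorted index sets (independent of stats::hclust)
brute_average_linkage_k2 <- function(x) {
  clusters <- as.list(seq_along(x))
  dmat <- as.matrix(dist(x))
  while (length(clusters) > 2) {
    best <- c(NA, NA)
    bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(dmat[clusters[[i]], clusters[[j]]])
        if (d < bestd) {
          bestd <- d
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]],
                                  clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
  }
  clusters[order(vapply(clusters, min, numeric(1)))]
}

# direct chi-square statistic of a contingency table (loop form)
chisq_direct <- function(x) {
  N <- sum(x)
  out <- 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      e <- sum(x[i, ]) * sum(x[, j]) / N
      out <- out + (x[i, j] - e)^2 / e
    }
  }
  out
}

# a synthetic genus x 13-class community: n_revj reverse-J genera
# (exponential-type class profiles) and n_dev deviating genera (unimodal
# Weibull-type profiles), multinomial-sampled counts
make_shape_community <- function(n_revj = 20, n_dev = 5, n_stems = 2000,
                                 seed = 42) {
  set.seed(seed)
  edges <- diameter_class_edges()
  mids <- edges$mid
  rows <- list()
  for (i in seq_len(n_revj)) {
    tau <- runif(1, 12, 30)
    p <- exp(-(mids - 30) / tau)
    rows[[sprintf("RevJ%02d", i)]] <- as.integer(
      rmultinom(1, n_stems, p / sum(p)))
  }
  for (i in seq_len(n_dev)) {
    k <- runif(1, 2.5, 4)
    lam <- runif(1, 80, 110)
    p <- dweibull(mids, k, lam)
    rows[[sprintf("Unim%02d", i)]] <- as.integer(
      rmultinom(1, n_stems, p / sum(p)))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- edges$label
  structure(m, class = c("genus_diameter_matrix", class(m)),
            class_edges = edges)
}

# study-condition defaults for the halted-recruitment regime
halt_history <- function(rate = 10000, end = 1850,
                         mortality = 0.025, census = 2000) {
  recruitment_history(data.frame(start = 1300, end = end, rate = rate),
                      mortality_rate = mortality, census_year = census)
}
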