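test_that("CA inertia equals chi-square over N (brute-force oracle)", {
  set.seed(4)
  for (i in 1:5) {
    x <- matrix(rpois(12, 10) + 1, 3, 4,
                dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
    ca <- correspondence_analysis(x)
    expect_equal(ca$total_inertia, chisq_direct(x) / sum(x),
                 tolerance = 1e-10)
    expect_equal(sum(ca$inertia), ca$total_inertia, tolerance = 1e-10)
    expect_true(all(diff(ca$inertia) <= 1e-12))  # decreasing axes
  }
})

test_that("independence gives zero inertia; degenerate input errors", {
  r <- c(10, 20, 30)
  cc <- c(1, 2, 3, 4)
  x <- outer(r, cc)
  ca <- correspondence_analysis(x)
  expect_lt(ca$total_inertia, 1e-12)
  expect_error(correspondence_analysis(matrix(5, 1, 4)), "degenerate")
  expect_error(correspondence_analysis(matrix(0, 3, 4)), "degenerate")
})

test_that("CA is equivariant to row permutation and scale invariant", {
  m <- make_shape_community(8, 3, seed = 10)
  ca <- correspondence_analysis(m)
  perm <- sample(nrow(m))
  ca_p <- correspondence_analysis(m[perm, ])
  expect_equal(ca_p$row_scores[rownames(m), ], ca$row_scores,
               tolerance = 1e-9)
  ca_s <- correspondence_analysis(m * 7)
  expect_equal(ca_s$total_inertia, ca$total_inertia, tolerance = 1e-10)
})

test_that("proportional rows receive identical row scores", {
  x <- rbind(a = c(10, 6, 3, 1), b = c(20, 12, 6, 2),
             c = c(1, 5, 9, 14))
  ca <- correspondence_analysis(x)
  expect_equal(ca$row_scores["a", ], ca$row_scores["b", ],
               tolerance = 1e-9)
})

test_that("CA agrees with an established implementation", {
  m <- make_shape_community(10, 4, seed = 17)
  ca <- correspondence_analysis(m)
  cca <- vegan::cca(unclass(m))
  ev <- as.numeric(cca$CA$eig)
  expect_equal(ca$inertia[seq_along(ev)], ev, tolerance = 1e-8,
               ignore_attr = TRUE)
  # first-axis scores match up to the sign convention
  v_scores <- vegan::scores(cca, display = "sites",
                            scaling = "sites", choices = 1)[, 1]
  r <- cor(ca$row_scores[, 1], v_scores[rownames(ca$row_scores)])
  expect_equal(abs(r), 1, tolerance = 1e-8)
})

test_that("first-axis clustering separates score groups", {
  sc <- c(g1 = -1, g2 = -1.1, g3 = 2, g4 = 2.2)
  cl <- cluster_first_axis(sc)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(cl$cluster[cl$genus %in% c("g1", "g2")][1],
               cl$cluster[cl$genus %in% c("g1", "g2")][2])
  expect_equal(cl$cluster[cl$genus %in% c("g3", "g4")][1],
               cl$cluster[cl$genus %in% c("g3", "g4")][2])
  expect_error(cluster_first_axis(c(a = 1, b = 1, c = 1)),
               "no separation")
  expect_error(cluster_first_axis(c(a = 1)), "at least two")
})

test_that("average-linkage 2-group cut matches a brute-force oracle", {
  set.seed(33)
  for (i in 1:10) {
    x <- round(rnorm(5), 3)
    names(x) <- paste0("g", 1:5)
    cl <- cluster_first_axis(x)
    grp <- split(seq_along(x), cl$cluster[match(names(x), cl$genus)])
    grp <- lapply(grp, sort)
    oracle <- brute_average_linkage_k2(unname(x))
    match_fwd <- identical(unname(grp), oracle) ||
      identical(unname(grp[2:1]), oracle)
    expect_true(match_fwd, info = paste("draw", i))
  }
})

test_that("unimodal genera are isolated from reverse-J genera", {
  m <- make_shape_community(20, 5, seed = 42)
  ca <- correspondence_analysis(m)
  cl <- cluster_first_axis(ca$row_scores[, 1], counts = m)
  dev <- cl$genus[cl$label == "deviating"]
  expect_setequal(dev, grep("^Unim", rownames(m), value = TRUE))
})

test_that("the direct shape heuristic reads distributions correctly", {
  expect_equal(classify_shape_direct(c(100, 60, 35, 20, 12, 8, 5, 3, 2, 1,
                                       1, 0, 0)), "reverse_J")
  rising <- c(5, 10, 20, 40, 60, 45, 30, 18, 10, 5, 2, 1, 0)
  expect_equal(classify_shape_direct(rising), "deviating")
  # one small inversion (< 10%) is tolerated
  expect_equal(classify_shape_direct(c(100, 60, 63, 40, 20, 10, 5, 3, 2,
                                       1, 1, 0, 0)), "reverse_J")
  # discretized known densities
  mids <- diameter_class_edges()$mid
  wb <- dweibull(mids, 2, 90)
  expect_equal(classify_shape_direct(round(1e4 * wb / sum(wb))),
               "deviating")
  ex <- dexp(mids - 30, 1 / 25)
  expect_equal(classify_shape_direct(round(1e4 * ex / sum(ex))),
               "reverse_J")
  expect_error(classify_shape_direct(rep(0, 13)), "at least one stem")
})

test_that("CA clustering agrees with the direct heuristic on clear data", {
  # stem counts per genus at the scale of a regional inventory
  m <- make_shape_community(20, 5, seed = 7, n_stems = 10000)
  ca <- correspondence_analysis(m)
  cl <- cluster_first_axis(ca$row_scores[, 1], counts = m)
  direct <- vapply(rownames(m), function(g) classify_shape_direct(m[g, ]),
                   character(1))
  agree <- mean(cl$label[match(rownames(m), cl$genus)] == direct)
  expect_gte(agree, 0.95)
})
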