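# Structure analysis: correspondence analysis of the genus x diameter-class
# abundance matrix, average-linkage clustering of the first-axis scores into
# two groups (reverse-J vs deviating), and a direct monotonicity heuristic.

#' Correspondence analysis of an abundance matrix
#'
#' Standard CA: the matrix of standardized residuals
#' \eqn{S = D_r^{-1/2} (P - r c^T) D_c^{-1/2}} (with \eqn{P} the relative
#' frequencies and \eqn{r}, \eqn{c} its margins) is decomposed by SVD;
#' principal inertias are the squared singular values and their sum is the
#' chi-square statistic of the table divided by its grand total. Row and
#' column scores are returned in principal coordinates.
#'
#' All-zero rows or columns are dropped (and reported via the
#' \code{dropped_rows} / \code{dropped_cols} elements). The sign of each
#' axis is fixed by requiring a positive correlation between the row scores
#' and the class-midpoint-weighted mean diameter of each row, so that
#' higher first-axis scores always mean larger-diameter distributions.
#'
#' @param x count matrix (genera x diameter classes), e.g. a
#'   [bin_diameters()] result.
#' @return list of class \code{ca_result}: \code{row_scores},
#'   \code{col_scores} (principal coordinates), \code{inertia} per axis,
#'   \code{total_inertia}, \code{dropped_rows}, \code{dropped_cols}.
#' @export
correspondence_analysis <- function(x) {
  edges <- attr(x, "class_edges")
  x <- unclass(as.matrix(x))
  storage.mode(x) <- "double"
  if (any(x < 0) || !all(is.finite(x))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  dropped_rows <- rownames(x)[rowSums(x) == 0]
  dropped_cols <- colnames(x)[colSums(x) == 0]
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2 || sum(x) == 0) {
    stop("degenerate matrix: correspondence analysis needs at least two ",
         "non-empty rows and columns", call. = FALSE)
  }
  N <- sum(x)
  P <- x / N
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  keep <- sv$d > max(dim(x)) * .Machine$double.eps * max(sv$d, 1)
  naxes <- sum(keep)
  d <- sv$d[keep]
  F <- sweep(sv$u[, keep, drop = FALSE], 2, d, `*`) / sqrt(r)
  G <- sweep(sv$v[, keep, drop = FALSE], 2, d, `*`) / sqrt(cc)
  # axis orientation: positive correlation with mean diameter per row
  mid <- if (!is.null(edges)) edges$mid else seq_len(ncol(x))
  row_mean_d <- as.numeric(x %*% mid) / rowSums(x)
  for (k in seq_len(naxes)) {
    s <- stats::cor(F[, k], row_mean_d)
    if (is.na(s) || s == 0) s <- sign(F[which.max(abs(F[, k])), k])
    if (s < 0) {
      F[, k] <- -F[, k]
      G[, k] <- -G[, k]
    }
  }
  if (naxes > 0) {
    dimnames(F) <- list(rownames(x), paste0("CA", seq_len(naxes)))
    dimnames(G) <- list(colnames(x), paste0("CA", seq_len(naxes)))
  }
  structure(list(row_scores = F, col_scores = G,
                 inertia = d^2, total_inertia = sum(sv$d^2),
                 dropped_rows = dropped_rows, dropped_cols = dropped_cols,
                 N = N), class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$row_scores), "rows x",
      nrow(x$col_scores), "columns\n")
  cat("  total inertia:", signif(x$total_inertia, 6),
      "(chi-square / N)\n")
  k <- min(4, length(x$inertia))
  if (k > 0) {
    cat("  inertia by axis:",
        paste(signif(x$inertia[seq_len(k)], 4), collapse = ", "),
        if (length(x$inertia) > k) "..." else "", "\n")
  }
  invisible(x)
}

#' Two-group clustering of first-axis scores
#'
#' Hierarchical agglomerative clustering (Euclidean distance, average
#' linkage) of the per-genus first-axis CA scores, cut into two groups. The
#' group whose diameter distributions load less on the first (smallest)
#' diameter class — the lower mean first-class-to-total ratio — is labelled
#' \code{deviating} (flat or unimodal structure); the other group, with
#' stems concentrated in the small classes, is the \code{reverse_J} group.
#' Without a count matrix the group with the higher mean score (larger
#' diameters under the CA sign convention) is labelled \code{deviating}.
#'
#' @param scores named numeric vector of first-axis scores (names = genera).
#' @param counts optional genus x class count matrix used for the labelling
#'   rule; rows are matched to \code{names(scores)}.
#' @return data frame of class \code{shape_classification} with columns
#'   \code{genus}, \code{axis1_score}, \code{cluster}, \code{label};
#'   attribute \code{linkage_height} holds the final merge height.
#' @export
cluster_first_axis <- function(scores, counts = NULL) {
  if (length(scores) < 2) stop("need at least two genera", call. = FALSE)
  if (is.null(names(scores))) names(scores) <- paste0("g", seq_along(scores))
  if (diff(range(scores)) == 0) {
    stop("no separation: all first-axis scores are identical",
         call. = FALSE)
  }
  scores <- scores[order(names(scores))]  # deterministic tie handling
  hc <- stats::hclust(stats::dist(scores), method = "average")
  grp <- stats::cutree(hc, k = 2)
  lab <- label_clusters(scores, grp, counts)
  out <- data.frame(genus = names(scores), axis1_score = unname(scores),
                    cluster = unname(grp), label = unname(lab[grp]),
                    row.names = NULL)
  attr(out, "linkage_height") <- max(hc$height)
  attr(out, "hclust") <- hc
  class(out) <- c("shape_classification", "data.frame")
  out
}

label_clusters <- function(scores, grp, counts) {
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    i <- match(names(scores), rownames(counts))
    if (any(is.na(i))) {
      stop("counts matrix is missing some genera in `scores`",
           call. = FALSE)
    }
    ratio <- counts[i, 1] / rowSums(counts[i, , drop = FALSE])
    crit <- tapply(ratio, grp, mean)     # low first-class share = deviating
    deviating <- as.integer(names(which.min(crit)))
  } else {
    crit <- tapply(scores, grp, mean)    # high score = larger diameters
    deviating <- as.integer(names(which.max(crit)))
  }
  ifelse(seq_len(2) == deviating, "deviating", "reverse_J")
}

#' Direct shape heuristic for a diameter distribution
#'
#' A distribution is \code{reverse_J} when its class counts are
#' non-increasing across the twelve bounded classes, tolerating at most one
#' inversion smaller than 10\% in relative size; anything else (flat or
#' unimodal) is \code{deviating}. Used as an independent cross-check of the
#' CA + clustering classification.
#'
#' @param counts numeric vector of class counts (the 13-class convention;
#'   the open top class is ignored by the monotonicity check).
#' @param tol relative size below which a single inversion is tolerated.
#' @param noise_floor counts below this fraction of the fullest class are
#'   treated as zero before the monotonicity check, so that sampling noise
#'   in near-empty tail classes does not register as inversions.
#' @return \code{"reverse_J"} or \code{"deviating"}.
#' @export
classify_shape_direct <- function(counts, tol = 0.10, noise_floor = 0.01) {
  counts <- as.numeric(counts)
  if (sum(counts) <= 0) stop("need at least one stem", call. = FALSE)
  k <- min(length(counts), 12L)          # bounded classes only
  cc <- counts[seq_len(k)]
  cc[cc < noise_floor * max(cc)] <- 0
  up <- which(diff(cc) > 0)
  if (length(up) == 0) return("reverse_J")
  if (length(up) > 1) return("deviating")
  i <- up
  rel <- (cc[i + 1] - cc[i]) / max(cc[i], .Machine$double.eps)
  if (rel < tol) "reverse_J" else "deviating"
}
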