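# Inventory tables and the genus x diameter-class matrix.
# Inventories record every stem >= 30 cm dbh; stems are binned into
# 10-cm-wide classes [30,40), ..., [140,150) plus an open top class
# [150, Inf): 13 classes in all.

#' Diameter class edges
#'
#' The 13 half-open classes \[30,40), ..., \[140,150), \[150, Inf).
#' @return data frame with columns \code{lo}, \code{hi}, \code{label},
#'   \code{mid} (the open top class is given a nominal midpoint of 155 cm).
#' @export
diameter_class_edges <- function() {
  lo <- seq(30, 150, by = 10)
  hi <- c(seq(40, 150, by = 10), Inf)
  data.frame(lo = lo, hi = hi,
             label = ifelse(is.finite(hi),
                            sprintf("[%.0f,%.0f)", lo, hi),
                            sprintf("[%.0f,Inf)", lo)),
             mid = ifelse(is.finite(hi), (lo + hi) / 2, lo + 5))
}

#' Read a forest-inventory CSV
#'
#' Expects columns \code{site}, \code{genus}, \code{dbh_cm}. Rows below the
#' 30 cm inventory threshold are dropped with a reported count (attribute
#' \code{n_below_threshold}); a non-numeric diameter is a hard error naming
#' the offending line.
#'
#' @param path path to the CSV file.
#' @param min_dbh inventory threshold (cm).
#' @return data frame of validated tree records.
#' @export
read_inventory <- function(path, min_dbh = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "genus", "dbh_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("inventory schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dbh <- suppressWarnings(as.numeric(df$dbh_cm))
  bad <- which(is.na(dbh) | !is.finite(dbh) | dbh <= 0)
  if (length(bad)) {
    stop("non-numeric or non-positive dbh_cm at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  df$dbh_cm <- dbh
  below <- dbh < min_dbh
  if (any(below)) {
    message(sum(below), " row(s) below the ", min_dbh,
            " cm inventory threshold rejected")
  }
  out <- df[!below, need, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_below_threshold") <- sum(below)
  out
}

#' Write an inventory CSV
#' @param trees tree table with \code{site}, \code{genus}, \code{dbh_cm}.
#' @param path output path.
#' @export
write_inventory <- function(trees, path) {
  utils::write.csv(trees[c("site", "genus", "dbh_cm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a genus-traits CSV
#'
#' Expects columns \code{genus}, \code{guild} (pioneer, NPLD, shade_bearer
#' or unknown), \code{phenology} (evergreen, deciduous or unknown) and
#' \code{wood_density} (g/cm^3, may be empty).
#'
#' @param path path to the CSV file.
#' @return validated traits data frame.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genus", "guild", "phenology", "wood_density")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("traits schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$guild <- ifelse(df$guild %in% c("pioneer", "NPLD", "shade_bearer"),
                     df$guild, "unknown")
  df$phenology <- ifelse(df$phenology %in% c("evergreen", "deciduous"),
                         df$phenology, "unknown")
  wd <- suppressWarnings(as.numeric(df$wood_density))
  if (any(!is.na(wd) & (wd <= 0 | wd >= 1.5))) {
    stop("wood_density values must lie in (0, 1.5) g/cm^3", call. = FALSE)
  }
  df$wood_density <- wd
  df[need]
}

#' Bin stems into the 13 diameter classes
#'
#' Every stem lands in exactly one half-open class; stems >= 150 cm all go
#' to the open top class. Row order is the lexicographic genus order.
#'
#' @param trees tree table with columns \code{genus} and \code{dbh_cm}, all
#'   diameters >= 30 cm.
#' @return integer matrix (genera x 13 classes) of class
#'   \code{genus_diameter_matrix}, with the class edges as attribute
#'   \code{class_edges}.
#' @export
bin_diameters <- function(trees) {
  stopifnot(all(c("genus", "dbh_cm") %in% names(trees)))
  if (nrow(trees) && any(trees$dbh_cm < 30)) {
    stop("all diameters must be >= 30 cm (inventory threshold)",
         call. = FALSE)
  }
  edges <- diameter_class_edges()
  cls <- cut(trees$dbh_cm, breaks = c(edges$lo, Inf), right = FALSE,
             labels = edges$label)
  tab <- table(factor(trees$genus), cls)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  structure(m, class = c("genus_diameter_matrix", class(m)),
            class_edges = edges)
}

# per-stem basal area at breast height, m^2: pi * (dbh/200)^2 (dbh in cm)
basal_area_m2 <- function(dbh_cm) pi * (dbh_cm / 200)^2

#' Per-genus composition summary
#'
#' For each genus: stem count, mean dbh (cm), mean per-stem basal area
#' (m^2; the mean of per-stem areas, not the area of the mean diameter),
#' and, when a traits table is supplied, guild, phenology and wood density.
#' Community-level means are attached as attribute \code{global}, both
#' genus-weighted (the mean of genus means; the default reading of
#' "a mean over all genera") and stem-weighted.
#'
#' @param trees tree table with \code{genus} and \code{dbh_cm}.
#' @param traits optional traits data frame (see [read_traits()]).
#' @return data frame, one row per genus, with attribute \code{global}.
#' @export
summarize_genus <- function(trees, traits = NULL) {
  stopifnot(nrow(trees) > 0)
  sp <- split(trees$dbh_cm, factor(trees$genus))
  out <- data.frame(
    genus = names(sp),
    n_stems = vapply(sp, length, integer(1)),
    mean_dbh_cm = vapply(sp, mean, numeric(1)),
    mean_basal_area_m2 = vapply(sp, function(d) mean(basal_area_m2(d)),
                                numeric(1)),
    row.names = NULL)
  if (!is.null(traits)) {
    i <- match(out$genus, traits$genus)
    out$guild <- ifelse(is.na(i), "unknown", traits$guild[i])
    out$phenology <- ifelse(is.na(i), "unknown", traits$phenology[i])
    out$wood_density <- traits$wood_density[i]
  }
  attr(out, "global") <- list(
    mean_dbh_genus = mean(out$mean_dbh_cm),
    mean_dbh_stem = mean(trees$dbh_cm),
    mean_basal_area_genus = mean(out$mean_basal_area_m2),
    mean_basal_area_stem = mean(basal_area_m2(trees$dbh_cm)))
  out
}

#' Share of stems belonging to a set of genera
#'
#' @param trees tree table with a \code{genus} column.
#' @param genera character vector of genus names (may be empty).
#' @return percentage of stems, \code{100 * n(listed) / n(all)}.
#' @examples
#' tr <- data.frame(genus = c("A", "A", "B", "C"), dbh_cm = 30:33)
#' species_share(tr, c("A", "B")) # 75
#' @export
species_share <- function(trees, genera) {
  if (!nrow(trees)) stop("empty tree table", call. = FALSE)
  100 * sum(trees$genus %in% genera) / nrow(trees)
}
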