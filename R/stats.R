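#' Micronucleus frequency
#'
#' Percentage of micronucleated cells among all scored cells, rounded to two
#' decimals.
#'
#' @param mn_cells Number of micronucleated cells.
#' @param total_cells Number of scored cells (>= 1).
#' @return Percentage, rounded to 2 decimal places.
#' @export
#' @examples
#' mn_percentage(11, 1555)  # 0.71
mn_percentage <- function(mn_cells, total_cells) {
  if (any(total_cells < 1)) stop("total_cells must be >= 1", call. = FALSE)
  if (any(mn_cells < 0) || any(mn_cells > total_cells))
    stop("mn_cells must lie in 0..total_cells", call. = FALSE)
  round(100 * mn_cells / total_cells, 2)
}

#' Relative viability
#'
#' Cytotoxicity proxy: the mean number of cells per image of a treated group
#' expressed as a percentage of the control group's mean cells per image,
#' rounded to an integer.
#'
#' @param group_total,group_images Total cells and image count of the
#'   treated group.
#' @param control_total,control_images Total cells and image count of the
#'   control group.
#' @return Integer percentage.
#' @export
#' @examples
#' relative_viability(1155, 187, 1555, 45)  # 18
relative_viability <- function(group_total, group_images,
                               control_total, control_images) {
  counts <- c(group_total, group_images, control_total, control_images)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  as.integer(round(100 * (group_total / group_images) /
                     (control_total / control_images)))
}

#' Significance star label
#'
#' Maps a p-value onto the conventional star labels: `***` below 0.005,
#' `**` below 0.01, `*` below 0.05, empty otherwise.
#'
#' @param p A p-value.
#' @return Character label.
#' @export
star_label <- function(p) {
  stopifnot(length(p) == 1L, !is.na(p))
  if (p < 0.005) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' One-sided pooled-variance two-sample t-test
#'
#' Classic Student t-test (pooled variance, independent samples) with a
#' one-sided alternative, the form used to compare per-image counts between
#' two counting methods. The direction is an explicit argument and is never
#' inferred from the data; the default tests whether the first sample's mean
#' exceeds the second's. Degenerate input with zero pooled variance and equal
#' means returns `t = 0, p = 0.5`.
#'
#' @param a,b Numeric vectors of per-image values (each length >= 2).
#' @param alternative `"greater"` (mean of `a` exceeds mean of `b`) or
#'   `"less"`.
#' @return Object of class `mn_t_test`: list with `t`, `p`, `star`, `df`,
#'   `n_a`, `n_b`, `alternative`.
#' @export
one_sided_t_test <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values", call. = FALSE)
  df <- length(a) + length(b) - 2L
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    if (mean(a) == mean(b)) {
      t_stat <- 0; p <- 0.5
    } else {
      t_stat <- sign(mean(a) - mean(b)) * Inf
      p <- if (alternative == "greater") as.numeric(t_stat < 0) else as.numeric(t_stat > 0)
    }
  } else {
    res <- stats::t.test(a, b, var.equal = TRUE, alternative = alternative)
    t_stat <- unname(res$statistic)
    p <- res$p.value
  }
  structure(list(t = t_stat, p = p, star = star_label(p), df = df,
                 n_a = length(a), n_b = length(b), alternative = alternative),
            class = "mn_t_test")
}

#' @export
print.mn_t_test <- function(x, ...) {
  cat(sprintf("Student t-test (pooled, one-sided %s): t = %.4g, df = %d, p = %.4g %s\n",
              x$alternative, x$t, x$df, x$p, x$star))
  invisible(x)
}

#' Coefficient of determination between two count series
#'
#' Square of the Pearson correlation, used to compare per-image counts from
#' two counting methods. Sign of the association is ignored.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be constant.
#' @return R-squared in \[0, 1\].
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("R-squared is undefined for a constant series", call. = FALSE)
  stats::cor(x, y)^2
}

#' Build a dose-group summary table
#'
#' Aggregates per-image counts into one row per dose group: image count,
#' total cells, micronucleated cells, micronucleus frequency and relative
#' viability against the control group. When a second counting method's
#' per-image micronucleated-cell counts are supplied, each group also gets
#' that method's totals, a one-sided pooled t-test (first method over the
#' second) and its star label.
#'
#' @param counts data.frame of per-image counts with columns `group`,
#'   `image`, `total_cells`, `mn_cells`.
#' @param control Label of the control group (must be present).
#' @param reference Optional data.frame in the same layout from a second
#'   counting method (e.g. manual scoring), matched by `group` and `image`.
#' @param alternative Direction of the per-group t-test comparing `counts`
#'   (first) against `reference` (second).
#' @return data.frame with one row per group.
#' @export
build_table <- function(counts, control, reference = NULL,
                        alternative = "greater") {
  need <- c("group", "image", "total_cells", "mn_cells")
  if (!all(need %in% names(counts)))
    stop("counts needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!control %in% counts$group)
    stop("control group '", control, "' not present", call. = FALSE)
  groups <- unique(counts$group)
  ctl <- counts[counts$group == control, ]
  rows <- lapply(groups, function(g) {
    gg <- counts[counts$group == g, ]
    row <- data.frame(
      group = g,
      n_images = nrow(gg),
      total_cells = sum(gg$total_cells),
      mn_cells = sum(gg$mn_cells),
      mn_percent = mn_percentage(sum(gg$mn_cells), sum(gg$total_cells)),
      viability = relative_viability(sum(gg$total_cells), nrow(gg),
                                     sum(ctl$total_cells), nrow(ctl))
    )
    if (!is.null(reference)) {
      rr <- reference[reference$group == g, ]
      mrg <- merge(gg, rr, by = "image", suffixes = c("", "_ref"))
      tt <- if (nrow(mrg) >= 2L)
        one_sided_t_test(mrg$mn_cells, mrg$mn_cells_ref, alternative)
      else list(p = NA_real_, star = "")
      row$ref_total_cells <- sum(rr$total_cells)
      row$ref_mn_cells <- sum(rr$mn_cells)
      row$ref_mn_percent <- mn_percentage(sum(rr$mn_cells), sum(rr$total_cells))
      row$p_value <- tt$p
      row$star <- tt$star
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published reference counts for four model clastogens
#'
#' Manual and automated per-group counts from a published acridine-orange
#' micronucleus assay in CHL/IU cells dosed with hydrogen peroxide, potassium
#' chromate, mitomycin C and methyl methanesulfonate, shipped as a plain-text
#' table. Columns give, per dose group: the number of photographs, the
#' manual total-cell and micronucleated-cell counts with the published
#' micronucleus frequency, the automated counts for the initial analysis,
#' individual reanalysis and batch reanalysis, the initial-analysis
#' significance stars, and the published relative viability.
#'
#' @return data.frame with one row per dose group.
#' @export
mn_reference_counts <- function() {
  path <- system.file("extdata", "chl_mn_assay_counts.tsv", package = "mncount",
                      mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
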