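# Feature identifier grammar, feature-grid construction, outcome derivation and
# tabular I/O.  Feature columns are named "ROI.METRIC.REGION" (e.g.
# "Amyg.CBF.sub"); regions are cortical ("cor"), subcortical ("sub") and white
# matter ("wm"), and each region admits only a fixed subset of the eight
# imaging metrics.

#' Imaging metrics admitted in each brain region
#'
#' Cortical grey matter carries cortical thickness (CT), fractal
#' dimensionality (FD), free water (FW), fractional anisotropy (FA), mean
#' diffusivity (MD), cerebral blood flow (CBF) and cerebrovascular reactivity
#' (CVR); subcortical grey matter replaces CT with volume (Vol); white matter
#' carries the diffusion metrics FW, FA and MD only.
#'
#' @return Named list mapping region code (`cor`, `sub`, `wm`) to a character
#'   vector of metric codes, in canonical order.
#' @export
region_metric_sets <- function() {
  list(
    cor = c("CT", "FD", "FW", "FA", "MD", "CBF", "CVR"),
    sub = c("Vol", "FD", "FW", "FA", "MD", "CBF", "CVR"),
    wm  = c("FW", "FA", "MD")
  )
}

#' All imaging metric codes
#' @return Character vector of the eight metric codes in canonical order.
#' @export
all_metrics <- function() c("Vol", "CT", "FD", "FW", "FA", "MD", "CBF", "CVR")

# canonical ROI form: hyphens folded to underscores
canonical_roi <- function(roi) gsub("-", "_", roi, fixed = TRUE)

#' Parse a feature identifier
#'
#' Splits an identifier of the form `ROI.METRIC.REGION` into its components
#' and validates the metric code, the region code and their compatibility.
#' ROI codes are kept verbatim except that hyphens and underscores are treated
#' as equivalent (canonical form uses the underscore, so `"IFG-O"` and
#' `"IFG_O"` name the same ROI).
#'
#' @param id Character scalar, e.g. `"Amyg.CBF.sub"`.
#' @return A `feature_descriptor`: list with fields `feature_id` (canonical),
#'   `roi`, `metric`, `region`.
#' @examples
#' parse_feature_id("Amyg.CBF.sub")
#' parse_feature_id("PLIC.FA.wm")
#' @export
parse_feature_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, !is.na(id))
  parts <- strsplit(id, ".", fixed = TRUE)[[1L]]
  if (length(parts) != 3L || any(!nzchar(parts))) {
    stop("malformed feature id '", id,
         "': expected 'ROI.METRIC.REGION' with nonempty segments",
         call. = FALSE)
  }
  roi <- canonical_roi(parts[1L])
  metric <- parts[2L]
  region <- parts[3L]
  if (!metric %in% all_metrics()) {
    stop("unknown metric code '", metric, "' in feature id '", id, "'",
         call. = FALSE)
  }
  rms <- region_metric_sets()
  if (!region %in% names(rms)) {
    stop("unknown region code '", region, "' in feature id '", id,
         "' (expected cor, sub or wm)", call. = FALSE)
  }
  if (!metric %in% rms[[region]]) {
    stop("incompatible metric/region pair in feature id '", id, "': ",
         metric, " is not defined for region '", region, "'", call. = FALSE)
  }
  structure(
    list(feature_id = paste(roi, metric, region, sep = "."),
         roi = roi, metric = metric, region = region),
    class = "feature_descriptor"
  )
}

#' Format a feature descriptor back to its canonical identifier
#' @param desc A `feature_descriptor` (or a list with `roi`, `metric`,
#'   `region`).
#' @return Character scalar canonical id.
#' @export
format_feature_id <- function(desc) {
  paste(canonical_roi(desc$roi), desc$metric, desc$region, sep = ".")
}

#' @export
print.feature_descriptor <- function(x, ...) {
  cat("<feature> ", x$feature_id, "  (ROI ", x$roi, ", metric ", x$metric,
      ", region ", x$region, ")\n", sep = "")
  invisible(x)
}

#' Build the full feature grid from per-region ROI lists
#'
#' Forms the cross product of each region's ROI list with that region's
#' admitted metric set, in deterministic order: region (cortical, subcortical,
#' white matter), then metric (canonical order within region), then ROI (input
#' order).
#'
#' @param cortical_rois,subcortical_rois,wm_rois Character vectors of ROI
#'   codes, unique within each region.
#' @return A `data.frame` with columns `feature_id`, `roi`, `metric`,
#'   `region`, one row per feature.
#' @examples
#' grid <- build_feature_grid(c("FRP", "PUC"), c("Amyg"), c("PLIC"))
#' nrow(grid)  # 2*7 + 1*7 + 1*3 = 24
#' @export
build_feature_grid <- function(cortical_rois, subcortical_rois, wm_rois) {
  rois <- list(cor = canonical_roi(cortical_rois),
               sub = canonical_roi(subcortical_rois),
               wm  = canonical_roi(wm_rois))
  for (rg in names(rois)) {
    if (length(rois[[rg]]) == 0L) {
      stop("empty ROI list for region '", rg, "'", call. = FALSE)
    }
    if (anyDuplicated(rois[[rg]])) {
      stop("duplicate ROI within region '", rg, "': ",
           paste(unique(rois[[rg]][duplicated(rois[[rg]])]), collapse = ", "),
           call. = FALSE)
    }
  }
  rms <- region_metric_sets()
  out <- do.call(rbind, lapply(names(rms), function(rg) {
    do.call(rbind, lapply(rms[[rg]], function(m) {
      data.frame(feature_id = paste(rois[[rg]], m, rg, sep = "."),
                 roi = rois[[rg]], metric = m, region = rg,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' The default 25-ROI grid (11 cortical, 7 subcortical, 7 white matter)
#'
#' Harvard-Oxford-style ROI panel yielding 147 features:
#' 77 cortical, 49 subcortical and 21 white-matter.
#'
#' @return Feature-grid `data.frame` (see [build_feature_grid()]).
#' @export
default_feature_grid <- function() {
  build_feature_grid(
    cortical_rois = c("FRP", "IFG_O", "STG", "POC", "PHG", "LNG",
                      "ICX", "LOC", "TMP", "SPL", "PUC"),
    subcortical_rois = c("CN", "PUT", "GP", "TH", "Amyg", "AccN", "Hippo"),
    wm_rois = c("SCC", "GCC", "BCC", "PLIC", "ALIC", "SLF", "ACR")
  )
}

#' Construct a validated subject-by-feature table
#'
#' @param values Numeric matrix, subjects in rows (rownames = subject ids),
#'   features in columns (colnames = feature ids).
#' @param descriptors Optional feature-grid `data.frame`; parsed from the
#'   column names when omitted.
#' @param analysis Logical; when `TRUE` (analysis mode) missing or non-finite
#'   cells are an error and at least 3 subjects are required.
#' @return A `feature_table`: list with `values`, `subject_ids`,
#'   `descriptors`.
#' @export
feature_table <- function(values, descriptors = NULL, analysis = TRUE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) {
    stop("feature table must carry subject ids as row names", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    stop("feature table must carry feature ids as column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate subject id: ",
         rownames(values)[duplicated(rownames(values))][1L], call. = FALSE)
  }
  if (is.null(descriptors)) {
    descriptors <- do.call(rbind, lapply(colnames(values), function(id) {
      d <- parse_feature_id(id)
      data.frame(feature_id = d$feature_id, roi = d$roi, metric = d$metric,
                 region = d$region, stringsAsFactors = FALSE)
    }))
  }
  if (nrow(descriptors) != ncol(values)) {
    stop("descriptor count (", nrow(descriptors),
         ") does not match feature count (", ncol(values), ")", call. = FALSE)
  }
  colnames(values) <- descriptors$feature_id
  if (analysis) {
    if (nrow(values) < 3L) {
      stop("analysis mode requires at least 3 subjects", call. = FALSE)
    }
    bad <- which(!is.finite(values), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop("missing or non-finite value at subject '",
           rownames(values)[bad[1L, 1L]], "', feature '",
           colnames(values)[bad[1L, 2L]], "'", call. = FALSE)
    }
  }
  structure(list(values = values,
                 subject_ids = rownames(values),
                 descriptors = descriptors),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$values), " subjects x ", ncol(x$values),
      " features (", paste(sprintf("%s: %d", names(table(x$descriptors$region)),
                                   as.integer(table(x$descriptors$region))),
                           collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# restrict a feature table to a subset of subjects and/or features
subset_feature_table <- function(tab, subjects = NULL, features = NULL) {
  v <- tab$values
  d <- tab$descriptors
  if (!is.null(features)) {
    keep <- match(features, d$feature_id)
    if (anyNA(keep)) {
      stop("unknown feature id(s): ",
           paste(features[is.na(keep)], collapse = ", "), call. = FALSE)
    }
    v <- v[, keep, drop = FALSE]
    d <- d[keep, , drop = FALSE]
    rownames(d) <- NULL
  }
  if (!is.null(subjects)) {
    keep <- match(subjects, rownames(v))
    if (anyNA(keep)) {
      stop("unknown subject id(s): ",
           paste(subjects[is.na(keep)], collapse = ", "), call. = FALSE)
    }
    v <- v[keep, , drop = FALSE]
  }
  feature_table(v, d)
}

#' Read a subject-by-feature table from CSV or TSV
#'
#' Expects a header row of feature ids with `subject_id` as the first column
#' and a fully numeric body. In analysis mode any missing cell is an error
#' naming the offending subject and feature; with
#' `drop_incomplete = TRUE` subjects with any missing value are removed first
#' (listwise deletion) and the number dropped is reported via `message()`.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"tsv"` (default inferred from the extension).
#' @param drop_incomplete Drop subjects with incomplete rows before
#'   validation.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, dialect = NULL, drop_incomplete = FALSE) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "subject_id") {
    stop("first column of a feature table must be 'subject_id'", call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate subject id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  body <- df[, -1L, drop = FALSE]
  non_num <- !vapply(body, is.numeric, logical(1L))
  if (any(non_num)) {
    col <- colnames(body)[non_num][1L]
    stop("non-numeric cell(s) in feature column '", col, "'", call. = FALSE)
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (drop_incomplete) {
    ok <- stats::complete.cases(m)
    if (any(!ok)) {
      message("dropping ", sum(!ok), " subject(s) with incomplete rows")
    }
    m <- m[ok, , drop = FALSE]
  }
  feature_table(m)
}

#' Write a feature table to CSV/TSV
#' @param tab A [feature_table()].
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_feature_table <- function(tab, path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  # 17 significant digits so finite doubles round-trip bit-identically
  body <- apply(tab$values, 2L, formatC, digits = 17L, format = "g")
  lines <- c(paste(c("subject_id", colnames(tab$values)), collapse = sep),
             apply(cbind(rownames(tab$values), body), 1L, paste,
                   collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort outcome table
#'
#' CSV with columns `subject_id`, `group` (`PWH` or `control`), `z_baseline`,
#' and optionally `z_followup` (blank where no follow-up visit exists).
#' [compute_delta_z()] is applied before returning.
#'
#' @param path File path.
#' @return Outcome `data.frame` with a `delta_z` column.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "z_baseline")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L) {
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"z_followup" %in% colnames(df)) df$z_followup <- NA_real_
  bad <- setdiff(unique(df$group), c("PWH", "control"))
  if (length(bad) > 0L) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df$z_baseline)) {
    stop("z_baseline missing for subject '",
         df$subject_id[is.na(df$z_baseline)][1L], "'", call. = FALSE)
  }
  compute_delta_z(df)
}

#' Derive the longitudinal change score
#'
#' Adds (or recomputes) `delta_z = z_followup - z_baseline`, so a positive
#' change is a cognitive improvement between baseline and the follow-up
#' visit. Rows without a follow-up score get `NA`. Idempotent.
#'
#' @param outcomes Outcome `data.frame` with `z_baseline` and optionally
#'   `z_followup`.
#' @return The table with a `delta_z` column; the number of PWH rows with a
#'   defined change score is attached as attribute `n_pwh_delta`.
#' @export
compute_delta_z <- function(outcomes) {
  stopifnot(is.data.frame(outcomes), "z_baseline" %in% colnames(outcomes))
  if (anyNA(outcomes$z_baseline)) {
    stop("z_baseline must be present for all rows", call. = FALSE)
  }
  if (!"z_followup" %in% colnames(outcomes)) outcomes$z_followup <- NA_real_
  outcomes$delta_z <- outcomes$z_followup - outcomes$z_baseline
  attr(outcomes, "n_pwh_delta") <-
    sum(outcomes$group == "PWH" & !is.na(outcomes$delta_z))
  outcomes
}

#' Write an adjusted-weight report
#'
#' Five-column CSV layout: `feature_id`, `adjusted_weight`,
#' `unadjusted_weight`, `mean`, `sd`.
#'
#' @param report A ranked weight report (see [rank_and_select()]) or any
#'   `data.frame` with those five columns.
#' @param path Output path.
#' @export
write_weight_table <- function(report, path) {
  need <- c("feature_id", "adjusted_weight", "unadjusted_weight", "mean", "sd")
  miss <- setdiff(need, colnames(report))
  if (length(miss) > 0L) {
    stop("weight report missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(report[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
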