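#' @name feature_table
#' @title Feature tables
#' @description
#' A feature table is a plain `data.frame` with one row per subject,
#' the metadata columns of [metadata_columns()] and either the 153 raw or
#' the 77 hemisphere-averaged feature columns of [feature_schema()].
#' The `feature_kind` attribute records which layout is present.
NULL

sex_dialect <- list(
  male   = c("male", "m", "1"),
  female = c("female", "f", "2", "0"))
dx_dialect <- list(
  SZ = c("sz", "case", "patient", "scz"),
  HC = c("hc", "control", "ctrl", "healthy"))

normalize_levels <- function(x, dialect, what) {
  out <- rep(NA_character_, length(x))
  lx <- tolower(trimws(as.character(x)))
  for (lev in names(dialect)) {
    out[lx %in% c(tolower(lev), dialect[[lev]])] <- lev
  }
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0L) {
    stop("unrecognised ", what, " value '", x[bad[1]], "' at row ", bad[1])
  }
  out
}

table_kind <- function(table) {
  sch <- feature_schema()
  if (all(sch$raw %in% names(table))) return("raw")
  if (all(sch$averaged %in% names(table))) return("averaged")
  stop("table has neither the full raw (153) nor averaged (77) feature set")
}

#' Validate a feature table
#'
#' Checks the contract every downstream stage relies on: unique subject ids,
#' complete core metadata (age, sex, dx, site), canonical sex/dx levels,
#' and finite, positive feature values.
#'
#' @param table data.frame to validate.
#' @return the table, invisibly, with a `feature_kind` attribute set.
#' @export
validate_feature_table <- function(table) {
  req <- required_metadata()
  missing <- setdiff(req, names(table))
  if (length(missing) > 0L) {
    stop("missing required metadata column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(table$subject_id)) {
    d <- table$subject_id[duplicated(table$subject_id)][1]
    stop("duplicate subject_id: ", d)
  }
  for (col in c("age", "sex", "dx", "site")) {
    if (anyNA(table[[col]])) {
      stop("missing values in required metadata column '", col, "' at row ",
           which(is.na(table[[col]]))[1])
    }
  }
  if (!all(table$sex %in% c("male", "female"))) {
    stop("sex must be 'male'/'female'; found '",
         setdiff(unique(table$sex), c("male", "female"))[1], "'")
  }
  if (!all(table$dx %in% c("SZ", "HC"))) {
    stop("dx must be 'SZ'/'HC'; found '",
         setdiff(unique(table$dx), c("SZ", "HC"))[1], "'")
  }
  kind <- table_kind(table)
  m <- feature_matrix(table, kind)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("non-finite feature value in '", colnames(m)[bad[2]],
         "' at row ", bad[1])
  }
  if (any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive feature value in '", colnames(m)[bad[2]],
         "' at row ", bad[1])
  }
  attr(table, "feature_kind") <- kind
  invisible(table)
}

#' Average left and right hemispheres
#'
#' Replaces each homologous left/right column pair by its mean
#' (left + right) / 2 and passes ICV through, reducing 153 raw features to
#' the 77 used for modelling. Idempotent: a table already in the averaged
#' layout is returned unchanged.
#'
#' @param table feature table with the 153 raw columns (or 77 averaged).
#' @return feature table with 77 averaged feature columns, metadata retained.
#' @examples
#' cfg <- generator_config(seed = 1)
#' raw <- generate_training_sample(cfg)
#' avg <- average_hemispheres(raw)
#' length(intersect(names(avg), feature_schema()$averaged))  # 77
#' @export
average_hemispheres <- function(table) {
  sch <- feature_schema()
  if (all(sch$averaged %in% names(table)) && !all(sch$raw %in% names(table))) {
    attr(table, "feature_kind") <- "averaged"
    return(table)
  }
  missing <- setdiff(sch$raw, names(table))
  if (length(missing) > 0L) {
    stop("cannot average hemispheres; missing raw column(s): ",
         paste(missing, collapse = ", "))
  }
  meta <- intersect(metadata_columns(), names(table))
  out <- table[, meta, drop = FALSE]
  for (i in seq_len(nrow(sch$pairs))) {
    p <- sch$pairs[i, ]
    out[[p$avg]] <- (table[[p$left]] + table[[p$right]]) / 2
  }
  out$icv <- table$icv
  attr(out, "feature_kind") <- "averaged"
  out
}

#' Read a cohort feature table from delimited text
#'
#' Accepts CSV or TSV (by extension, or `sep`) with a header row. Sex may be
#' coded `male`/`female`, `M`/`F` (any case); diagnosis `SZ`/`HC`,
#' `case`/`control` or `patient`/`control`; both are normalised to the
#' canonical `male`/`female` and `SZ`/`HC` labels. The table is validated
#' on read.
#'
#' @param path file path.
#' @param sep field separator; default inferred from extension
#'   (`.csv` vs `.tsv`/`.txt`).
#' @return validated feature table.
#' @export
read_feature_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  req <- required_metadata()
  missing <- setdiff(req, names(tab))
  if (length(missing) > 0L) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  tab$subject_id <- as.character(tab$subject_id)
  tab$sex <- normalize_levels(tab$sex, sex_dialect, "sex")
  tab$dx  <- normalize_levels(tab$dx, dx_dialect, "dx")
  if (!is.numeric(tab$age)) {
    suppressWarnings(age <- as.numeric(tab$age))
    if (anyNA(age) && !anyNA(tab$age)) {
      stop("non-numeric age at row ", which(is.na(age))[1])
    }
    tab$age <- age
  }
  kind <- table_kind(tab)
  feats <- if (kind == "raw") feature_schema()$raw else feature_schema()$averaged
  for (f in feats) {
    if (!is.numeric(tab[[f]])) {
      suppressWarnings(v <- as.numeric(tab[[f]]))
      if (anyNA(v) && !anyNA(tab[[f]])) {
        stop("non-numeric value in feature '", f, "' at row ",
             which(is.na(v))[1])
      }
      tab[[f]] <- v
    }
  }
  validate_feature_table(tab)
  attr(tab, "feature_kind") <- kind
  tab
}

#' Write a feature table to delimited text
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces every double bit-exactly.
#'
#' @param table feature table.
#' @param path output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- as.data.frame(table, stringsAsFactors = FALSE)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- formatC(out[[col]], digits = 17, format = "g")
      v[is.na(out[[col]])] <- NA
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Flag statistical outlier cells
#'
#' Advisory quality-control screen: flags any feature value more than
#' `z_threshold` standard deviations from its feature mean, computed within
#' cohort x diagnosis group (the strata in which values are expected to be
#' homogeneous). Flags are never acted on automatically.
#'
#' @param table averaged feature table.
#' @param z_threshold flag threshold in SD units (default 3).
#' @param by metadata columns defining the strata (default cohort and dx).
#' @return logical matrix, subjects x 77 features; TRUE marks a flagged cell.
#'   Features with zero variance within a stratum are left unflagged there
#'   (with a warning).
#' @export
flag_outliers <- function(table, z_threshold = 3, by = c("cohort", "dx")) {
  stopifnot(z_threshold > 0)
  m <- feature_matrix(table, "averaged")
  strata <- interaction(table[, by, drop = FALSE], drop = TRUE)
  flags <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  degenerate <- character(0)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    sub <- m[idx, , drop = FALSE]
    mu <- colMeans(sub)
    sd <- apply(sub, 2, stats::sd)
    zero <- !is.finite(sd) | sd == 0
    degenerate <- union(degenerate, colnames(m)[zero])
    sd[zero] <- Inf  # zero-variance features cannot be flagged
    z <- abs(sweep(sweep(sub, 2, mu, "-"), 2, sd, "/"))
    flags[idx, ] <- z > z_threshold
  }
  if (length(degenerate) > 0L) {
    warning("zero within-stratum SD for feature(s) ",
            paste(utils::head(degenerate, 5L), collapse = ", "),
            "; left unflagged")
  }
  flags
}
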