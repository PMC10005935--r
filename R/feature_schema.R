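#' Feature schema for regional brain morphometry tables
#'
#' The analysis operates on FreeSurfer-style regional measures: cortical
#' thickness and surface area for the 34 Desikan-Killiany regions per
#' hemisphere, seven bilateral subcortical gray-matter volumes, the two
#' lateral ventricles and total intracranial volume (ICV). The raw layout has
#' 153 columns (68 thickness + 68 area + 14 subcortical + 2 ventricles + ICV);
#' the modelling layout averages homologous left/right pairs, giving
#' 34 + 34 + 7 + 1 + 1 = 77 features.
#'
#' @return A list with components:
#'   \item{raw}{character vector of the 153 canonical raw column names}
#'   \item{averaged}{character vector of the 77 canonical averaged names}
#'   \item{classes}{data.frame mapping each averaged feature to its class
#'     (`thickness`, `area`, `subcortical`, `ventricle`, `icv`) and units}
#'   \item{pairs}{data.frame with columns `avg`, `left`, `right` for the 76
#'     paired features (ICV is unpaired and passed through)}
#' @examples
#' sch <- feature_schema()
#' length(sch$raw)       # 153
#' length(sch$averaged)  # 77
#' table(sch$classes$class)
#' @export
feature_schema <- function() {
  cortical <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
  subcort <- c("thalamus", "caudate", "putamen", "pallidum", "hippocampus",
               "amygdala", "accumbens")

  avg_thick <- paste0(cortical, "_thick")
  avg_area  <- paste0(cortical, "_area")
  avg_vol   <- paste0(subcort, "_vol")
  averaged  <- c(avg_thick, avg_area, avg_vol, "latvent_vol", "icv")

  paired_avg <- c(avg_thick, avg_area, avg_vol, "latvent_vol")
  pairs <- data.frame(
    avg   = paired_avg,
    left  = paste0("lh_", paired_avg),
    right = paste0("rh_", paired_avg),
    stringsAsFactors = FALSE)
  # canonical raw order: lh/rh interleaved in averaged order, ICV last
  raw <- c(as.vector(t(as.matrix(pairs[, c("left", "right")]))), "icv")

  classes <- data.frame(
    feature = averaged,
    class = c(rep("thickness", 34), rep("area", 34), rep("subcortical", 7),
              "ventricle", "icv"),
    units = c(rep("mm", 34), rep("mm^2", 34), rep("mm^3", 9)),
    stringsAsFactors = FALSE)

  list(raw = raw, averaged = averaged, classes = classes, pairs = pairs)
}

#' Metadata columns recognised in feature tables
#'
#' @return Character vector of metadata column names. The first six
#'   (`subject_id`, `cohort`, `site`, `age`, `sex`, `dx`) are required; the
#'   rest (handedness and clinical variables) are optional and may be missing
#'   or NA for healthy controls.
#' @export
metadata_columns <- function() {
  c("subject_id", "cohort", "site", "age", "sex", "dx", "handedness",
    "onset", "duration", "panss_total", "sans_global", "saps_global",
    "ap_class", "cpz")
}

required_metadata <- function() metadata_columns()[1:6]

#' Extract the numeric feature matrix from a feature table
#'
#' @param table a feature table (data.frame) with averaged (77) or raw (153)
#'   feature columns under canonical names.
#' @param kind `"averaged"` (default) or `"raw"`.
#' @return numeric matrix, rows in table order (rownames = subject_id),
#'   columns in canonical schema order.
#' @export
feature_matrix <- function(table, kind = c("averaged", "raw")) {
  kind <- match.arg(kind)
  sch <- feature_schema()
  want <- if (kind == "averaged") sch$averaged else sch$raw
  missing <- setdiff(want, names(table))
  if (length(missing) > 0L) {
    stop("feature table is missing ", length(missing), " ", kind,
         " feature column(s): ", paste(utils::head(missing, 8L), collapse = ", "),
         if (length(missing) > 8L) ", ..." else "")
  }
  m <- as.matrix(table[, want, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(table$subject_id)
  m
}
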