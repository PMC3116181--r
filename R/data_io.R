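# Readers, validators and the bundled study dataset: composition tables
# (samples x 18 amino acids, percent), activity tables (one response per
# sample), and the 3-z physicochemical scale lookup.

#' Construct and validate a composition matrix
#'
#' A composition matrix holds the percent amino-acid composition of a panel
#' of protein hydrolysate samples: one row per sample, one column for each
#' of the 18 pooled codes in [aa_labels]. Values are percentages, so each
#' row is expected to sum to about 100; because printed compositions are
#' rounded and partial panels occur in practice, row sums outside
#' `[95, 105]` raise a warning by default (an error when
#' `row_sum_action = "error"`).
#'
#' @param values Numeric matrix or data frame, samples x amino acids, with
#'   column names drawn from [aa_labels] (order-insensitive).
#' @param sample_ids Optional character vector of sample labels; defaults to
#'   the row names of `values`, or `1..n`.
#' @param row_sum_action One of `"warn"`, `"error"`, `"none"`: how to treat
#'   rows whose sum falls outside `[95, 105]`.
#' @return A numeric matrix of class `"composition_matrix"` with rows in
#'   input order and columns in the canonical [aa_labels] order.
#' @export
composition_matrix <- function(values, sample_ids = NULL,
                               row_sum_action = c("warn", "error", "none")) {
  row_sum_action <- match.arg(row_sum_action)
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("composition values must be numeric", call. = FALSE)
  cn <- colnames(values)
  if (is.null(cn))
    stop("composition matrix needs amino-acid column names", call. = FALSE)
  if (anyDuplicated(cn))
    stop("duplicate amino-acid columns: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "), call. = FALSE)
  missing <- setdiff(aa_labels, cn)
  if (length(missing) > 0L)
    stop("missing amino-acid column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(cn, aa_labels)
  if (length(extra) > 0L)
    stop("unknown amino-acid column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  values <- values[, aa_labels, drop = FALSE]
  if (anyNA(values))
    stop("composition matrix contains missing values", call. = FALSE)
  if (any(values < 0))
    stop("composition values must be non-negative", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(values)))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids", call. = FALSE)
  rownames(values) <- as.character(sample_ids)
  rs <- rowSums(values)
  bad <- which(rs < 95 | rs > 105)
  if (length(bad) > 0L && row_sum_action != "none") {
    msg <- paste0("row sum outside [95, 105] for sample(s): ",
                  paste(sprintf("%s (%.2f)", rownames(values)[bad], rs[bad]),
                        collapse = ", "))
    if (row_sum_action == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(values, class = c("composition_matrix", "matrix", "array"))
}

#' Read an amino-acid composition table from delimited text
#'
#' Expects one header row naming the 18 pooled amino-acid codes (any column
#' order), a sample-id first column, decimal points, and `#` comment lines.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @inheritParams composition_matrix
#' @return A [composition_matrix].
#' @export
read_composition <- function(path, sep = ",",
                             row_sum_action = c("warn", "error", "none")) {
  tab <- read_table_checked(path, sep)
  vals <- parse_numeric_block(tab[, -1, drop = FALSE], path)
  composition_matrix(vals, sample_ids = as.character(tab[[1]]),
                     row_sum_action = match.arg(row_sum_action))
}

#' Construct an activity table
#'
#' One antioxidant response per sample: percent radical scavenging (DPPH,
#' hydrogen peroxide, superoxide) or absorbance at 700 nm (ferric reducing
#' antioxidant power, FRAP). The sample set may be a subset of a companion
#' composition matrix (assays are not always run on every sample), but no
#' value may be missing within the declared subset.
#'
#' @param sample_ids Character vector of sample labels.
#' @param values Numeric vector, one activity value per sample.
#' @param name Activity name, e.g. `"dpph"`, `"frap"`, `"h2o2"`,
#'   `"superoxide"`, or any user-defined label.
#' @param units Unit tag, e.g. `"percent"` or `"absorbance_700nm"`.
#' @return A data frame of class `"activity_table"` with columns
#'   `sample_id` and `value` and attributes `activity_name` and `units`.
#' @export
activity_table <- function(sample_ids, values, name, units = "percent") {
  sample_ids <- as.character(sample_ids)
  values <- as.numeric(values)
  if (length(sample_ids) != length(values))
    stop("sample_ids and values differ in length", call. = FALSE)
  if (anyNA(values))
    stop("activity '", name, "' has missing values", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in activity '", name, "'", call. = FALSE)
  out <- data.frame(sample_id = sample_ids, value = values,
                    stringsAsFactors = FALSE)
  structure(out, class = c("activity_table", "data.frame"),
            activity_name = name, units = units)
}

#' Read activity tables from delimited text
#'
#' Expects a sample-id first column and one column per activity. Missing
#' cells (empty or `NA`) mark samples on which that assay was not run; the
#' activity table is restricted to the assayed subset.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator.
#' @param units Named character vector mapping activity names to unit tags;
#'   activities not named default to `"percent"`.
#' @return Named list of [activity_table] objects, one per activity column.
#' @export
read_activities <- function(path, sep = ",", units = c(frap = "absorbance_700nm")) {
  tab <- read_table_checked(path, sep)
  ids <- as.character(tab[[1]])
  out <- list()
  for (nm in names(tab)[-1]) {
    v <- suppressWarnings(as.numeric(tab[[nm]]))
    bad <- which(!is.na(tab[[nm]]) & tab[[nm]] != "" & is.na(v))
    if (length(bad) > 0L)
      stop("non-numeric activity value in column '", nm, "', row ", bad[1L],
           call. = FALSE)
    keep <- !is.na(v)
    u <- if (nm %in% names(units)) units[[nm]] else "percent"
    out[[nm]] <- activity_table(ids[keep], v[keep], name = nm, units = u)
  }
  out
}

#' Read and pool a 3-z amino-acid scale table
#'
#' Reads per-amino-acid physicochemical principal-property scores (z1
#' hydrophilicity, z2 steric bulk/size, z3 electronic properties) for the 20
#' standard amino acids and pools them to the 18 codes of acid-hydrolysis
#' composition data: the `ASX` record is the arithmetic mean of the Asn and
#' Asp records, `GLX` the mean of Gln and Glu.
#'
#' The pooled table is checked against three known orderings of the Hellberg
#' scale (the five most electron-rich residues, the seven most hydrophobic,
#' the eight least bulky); a violation indicates a corrupted or mislabelled
#' scale file.
#'
#' @param path Path to a delimited file with columns `aa`, `z1`, `z2`, `z3`
#'   and 20 rows (codes `ALA`..`TRP` plus `ASN`, `ASP`, `GLN`, `GLU`).
#'   Defaults to the bundled Hellberg 1987 scale.
#' @param sep Field separator.
#' @return A data frame of class `"zscale_table"` with row names in
#'   [aa_labels] order and columns `z1`, `z2`, `z3`.
#' @export
read_zscales <- function(path = system.file("extdata", "hellberg_zscales.csv",
                                            package = "aapls"),
                         sep = ",") {
  tab <- read_table_checked(path, sep)
  need <- c("aa", "z1", "z2", "z3")
  if (!all(need %in% names(tab)))
    stop("z-scale table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$aa))
    stop("duplicate amino-acid row(s) in z-scale table: ",
         paste(unique(tab$aa[duplicated(tab$aa)]), collapse = ", "),
         call. = FALSE)
  std20 <- c(setdiff(aa_labels, c("ASX", "GLX")), "ASN", "ASP", "GLN", "GLU")
  missing <- setdiff(std20, tab$aa)
  if (length(missing) > 0L)
    stop("z-scale table missing amino acid(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  rownames(tab) <- tab$aa
  z <- as.matrix(tab[, c("z1", "z2", "z3")])
  if (!is.numeric(z) || anyNA(z))
    stop("non-numeric z-scale values", call. = FALSE)
  pooled <- z[setdiff(aa_labels, c("ASX", "GLX")), , drop = FALSE]
  pooled <- rbind(pooled,
                  ASX = colMeans(z[c("ASN", "ASP"), , drop = FALSE]),
                  GLX = colMeans(z[c("GLN", "GLU"), , drop = FALSE]))
  pooled <- pooled[aa_labels, , drop = FALSE]
  out <- as.data.frame(pooled)
  class(out) <- c("zscale_table", "data.frame")
  validate_zscale_orderings(out)
  out
}

# The Hellberg scale satisfies three published orderings; verifying them
# guards against swapped columns or mistyped values in user-supplied files.
validate_zscale_orderings <- function(z) {
  chk <- function(labels, values, decreasing, what) {
    v <- values[labels]
    ok <- if (decreasing) all(diff(v) < 0) else all(diff(v) > 0)
    if (!ok)
      stop("z-scale ordering violated (", what, "): expected ",
           paste(labels, collapse = if (decreasing) " > " else " < "),
           call. = FALSE)
  }
  z1 <- stats::setNames(z$z1, rownames(z))
  z2 <- stats::setNames(z$z2, rownames(z))
  z3 <- stats::setNames(z$z3, rownames(z))
  chk(c("CYS", "PRO", "ASX", "HIS", "TRP"), z3, TRUE,
      "z3 electronic: Cys > Pro > Asx > His > Trp")
  chk(c("PHE", "TRP", "ILE", "LEU", "VAL", "MET", "TYR"), z1, FALSE,
      "z1 hydrophobicity: Phe < Trp < Ile < Leu < Val < Met < Tyr")
  chk(c("GLY", "VAL", "THR", "ALA", "ILE", "SER", "LEU", "CYS"), z2, FALSE,
      "z2 bulk: Gly < Val < Thr < Ala < Ile < Ser < Leu < Cys")
  invisible(z)
}

#' Assemble a dataset of composition, activities and z-scales
#'
#' @param composition A [composition_matrix].
#' @param activities Named list of [activity_table] objects (may be empty).
#' @param zscales A z-scale table from [read_zscales].
#' @param groups_ref Optional reference matrix of published group sums used
#'   for cross-checking (as in [bundled_dataset()]).
#' @param notes Free-text provenance notes.
#' @return A list of class `"aa_dataset"`.
#' @export
aa_dataset <- function(composition, activities = list(),
                       zscales = read_zscales(), groups_ref = NULL,
                       notes = character()) {
  stopifnot(inherits(composition, "composition_matrix"))
  ids <- rownames(composition)
  for (nm in names(activities)) {
    act <- activities[[nm]]
    stopifnot(inherits(act, "activity_table"))
    stray <- setdiff(act$sample_id, ids)
    if (length(stray) > 0L)
      stop("activity '", nm, "' names sample(s) absent from the composition",
           " matrix: ", paste(stray, collapse = ", "), call. = FALSE)
  }
  structure(list(composition = composition, activities = activities,
                 zscales = zscales, groups_ref = groups_ref, notes = notes),
            class = "aa_dataset")
}

#' The bundled hydrolysate study dataset
#'
#' Sixteen food protein hydrolysates and peptide fractions (hempseed and pea
#' protein, fractionated by molecular size, hydrophobicity and cationic
#' character) with their percent amino-acid composition, the published
#' physicochemical group sums as a cross-check reference, and the Hellberg
#' 3-z scale. The compositions are used exactly as printed (no
#' re-normalisation of row sums), because the published group sums reproduce
#' only from the unnormalised entries.
#'
#' Antioxidant activity values (DPPH, FRAP, H2O2, superoxide) are not
#' redistributable with the package and ship empty; users holding the
#' original supplementary activity data can attach them with
#' `read_activities()` (a CSV with a `sample_id` column matching `1..16` and
#' one column per assay) via [with_activities()].
#'
#' @return An [aa_dataset] with 16 samples, empty `activities`, and the
#'   published group sums in `$groups_ref`.
#' @export
bundled_dataset <- function() {
  comp <- read_composition(system.file("extdata", "table3_aa_composition.csv",
                                       package = "aapls"))
  ref <- read_table_checked(system.file("extdata", "table4_gaa_reference.csv",
                                        package = "aapls"), ",")
  refm <- as.matrix(ref[, -1])
  rownames(refm) <- as.character(ref[[1]])
  aa_dataset(comp, activities = list(), zscales = read_zscales(),
             groups_ref = refm,
             notes = "16 hempseed/pea protein hydrolysates and fractions")
}

#' Attach activity tables to a dataset
#'
#' Convenience hook for users supplying their own activity measurements
#' (e.g. the original study's supplementary data) for a dataset whose
#' bundled activities are empty.
#'
#' @param dataset An [aa_dataset].
#' @param activities Named list of [activity_table] objects, or a file path
#'   passed to [read_activities()].
#' @param sep Field separator when `activities` is a path.
#' @return The dataset with activities attached (replacing any same-named
#'   existing tables).
#' @export
with_activities <- function(dataset, activities, sep = ",") {
  stopifnot(inherits(dataset, "aa_dataset"))
  if (is.character(activities) && length(activities) == 1L)
    activities <- read_activities(activities, sep = sep)
  acts <- dataset$activities
  for (nm in names(activities)) acts[[nm]] <- activities[[nm]]
  aa_dataset(dataset$composition, acts, dataset$zscales, dataset$groups_ref,
             dataset$notes)
}

# -- shared low-level helpers -------------------------------------------------

read_table_checked <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           strip.white = TRUE)
  if (ncol(tab) < 2L)
    stop("expected a sample-id column plus data columns in ", path,
         " (wrong separator?)", call. = FALSE)
  tab
}

parse_numeric_block <- function(df, path) {
  out <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad) > 0L)
      stop("non-numeric value '", df[[j]][bad[1L]], "' at row ", bad[1L],
           ", column '", names(df)[j], "' in ", path, call. = FALSE)
    out[, j] <- v
  }
  out
}
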