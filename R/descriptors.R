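# Descriptor (X-matrix) construction: individual amino acids (AA),
# physicochemical group sums (gAA), z-scale sum descriptors, and
# unit-variance autoscaling for modeling.

new_descriptor_matrix <- function(values, set_tags) {
  stopifnot(is.matrix(values), length(set_tags) == ncol(values),
            all(set_tags %in% c("AA", "gAA", "z")))
  if (anyDuplicated(colnames(values)))
    stop("duplicate descriptor column labels", call. = FALSE)
  structure(values, set_tags = set_tags,
            class = c("descriptor_matrix", "matrix", "array"))
}

#' Physicochemical group-sum descriptors (gAA)
#'
#' Sums the percent composition over the five physicochemical amino-acid
#' groups of [aa_groups]: sulfur-containing (SCAA = Cys + Met), positively
#' charged (PCAA = Arg + Lys + His), hydrophobic (HAA, ten residues),
#' acidic (AcAA = Asx + Glx) and aromatic (AAA = Phe + Tyr + Trp).
#'
#' @param composition A [composition_matrix].
#' @return A 5-column descriptor matrix (percent), samples in input order.
#' @export
group_sums <- function(composition) {
  stopifnot(inherits(composition, "composition_matrix"))
  vals <- vapply(aa_groups,
                 function(members) rowSums(composition[, members, drop = FALSE]),
                 numeric(nrow(composition)))
  vals <- matrix(vals, nrow = nrow(composition),
                 dimnames = list(rownames(composition), names(aa_groups)))
  new_descriptor_matrix(vals, rep("gAA", ncol(vals)))
}

#' Composition-weighted z-scale sum descriptors
#'
#' For each sample, the algebraic sum over the 18 amino acids of each
#' physicochemical z score weighted by percent composition:
#' `sum_zi = sum_X zi(X) * c_X`, with `c_X` the percent composition of
#' amino acid `X` (percent units, as reported — not fractions). The three
#' resulting columns summarise a hydrolysate's bulk hydrophilicity
#' (`sum_z1`), steric bulk (`sum_z2`) and electron richness (`sum_z3`), and
#' are linear in the composition.
#'
#' @param composition A [composition_matrix].
#' @param zscales A pooled 18-label z-scale table from [read_zscales].
#' @return A 3-column descriptor matrix (`sum_z1`, `sum_z2`, `sum_z3`).
#' @export
zscale_sums <- function(composition, zscales) {
  stopifnot(inherits(composition, "composition_matrix"))
  missing <- setdiff(aa_labels, rownames(zscales))
  if (length(missing) > 0L)
    stop("z-scale table missing label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  zmat <- as.matrix(zscales[aa_labels, c("z1", "z2", "z3")])
  vals <- unclass(composition)[, aa_labels, drop = FALSE] %*% zmat
  colnames(vals) <- zsum_labels
  new_descriptor_matrix(vals, rep("z", 3L))
}

#' Assemble the descriptor matrix for a given X set
#'
#' Builds the predictor block used for modeling: `"AA"` (the 18 individual
#' amino-acid columns), `"gAA"` (the 5 group sums), `"z"` (the 3 z-scale
#' sums), or `"all"` (synonym `"AA+gAA+z"`; 26 columns). The combined
#' column order is fixed — AA in canonical order, then the five groups,
#' then `sum_z1..sum_z3` — so that coefficient and VIP indices are stable.
#'
#' @param dataset An [aa_dataset].
#' @param x_set One of `"AA"`, `"gAA"`, `"z"`, `"all"` (or `"AA+gAA+z"`).
#' @return A descriptor matrix with a per-column set tag attribute.
#' @export
assemble_x <- function(dataset, x_set = "all") {
  stopifnot(inherits(dataset, "aa_dataset"))
  x_set <- normalize_x_set(x_set)
  comp <- dataset$composition
  blocks <- list()
  if (x_set %in% c("AA", "all")) {
    aa <- unclass(comp)[, aa_labels, drop = FALSE]
    blocks$AA <- new_descriptor_matrix(aa, rep("AA", ncol(aa)))
  }
  if (x_set %in% c("gAA", "all"))
    blocks$gAA <- group_sums(comp)
  if (x_set %in% c("z", "all"))
    blocks$z <- zscale_sums(comp, dataset$zscales)
  vals <- do.call(cbind, lapply(blocks, unclass))
  tags <- unlist(lapply(blocks, attr, "set_tags"), use.names = FALSE)
  colnames(vals) <- unlist(lapply(blocks, colnames), use.names = FALSE)
  rownames(vals) <- rownames(comp)
  new_descriptor_matrix(vals, tags)
}

#' Centre and scale descriptors and response to unit variance
#'
#' Autoscaling gives every descriptor equal a-priori weight in the latent
#' projection: each column is centred to mean zero and divided by its
#' sample standard deviation (n-1 denominator); the response is treated the
#' same way. The centring and scaling parameters are returned so that
#' predictions can be back-transformed to original units.
#'
#' A constant column cannot be autoscaled; it raises an error naming the
#' column rather than being dropped silently, because descriptor blocks
#' have fixed width and silent drops would corrupt coefficient bookkeeping.
#'
#' @param x Descriptor matrix (or plain numeric matrix with column names).
#' @param y Optional numeric response vector.
#' @return List with `x` (scaled matrix), `y` (scaled vector or `NULL`),
#'   and `params` (list of `x_center`, `x_scale`, `y_center`, `y_scale`).
#' @export
autoscale <- function(x, y = NULL) {
  x <- as.matrix(unclass(x))
  if (nrow(x) < 3L)
    stop("autoscaling needs at least 3 samples", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  const <- which(scl <= 0 | !is.finite(scl))
  if (length(const) > 0L)
    stop("constant column(s) cannot be autoscaled: ",
         paste(colnames(x)[const], collapse = ", "), call. = FALSE)
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  params <- list(x_center = ctr, x_scale = scl,
                 y_center = NULL, y_scale = NULL)
  ys <- NULL
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != nrow(x))
      stop("y length does not match number of rows of x", call. = FALSE)
    params$y_center <- mean(y)
    params$y_scale <- stats::sd(y)
    if (params$y_scale <= 0 || !is.finite(params$y_scale))
      stop("response has zero variance", call. = FALSE)
    ys <- (y - params$y_center) / params$y_scale
  }
  list(x = xs, y = ys, params = params)
}

#' Invert autoscaling
#'
#' @param x_scaled Scaled matrix (or `NULL`).
#' @param y_scaled Scaled response (or `NULL`).
#' @param params Scaling parameters from [autoscale].
#' @return List with back-transformed `x` and/or `y`.
#' @export
unscale <- function(x_scaled = NULL, y_scaled = NULL, params) {
  out <- list()
  if (!is.null(x_scaled))
    out$x <- sweep(sweep(as.matrix(x_scaled), 2L, params$x_scale, "*"),
                   2L, params$x_center, "+")
  if (!is.null(y_scaled))
    out$y <- y_scaled * params$y_scale + params$y_center
  out
}

#' Export a descriptor matrix to delimited text
#'
#' Writes the matrix with a `set` tag row recording which block (`AA`,
#' `gAA`, `z`) each column belongs to.
#'
#' @param x Descriptor matrix.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_descriptors <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "descriptor_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(x)), collapse = sep), con)
  writeLines(paste(c("#set", attr(x, "set_tags")), collapse = sep), con)
  utils::write.table(cbind(sample_id = rownames(x),
                           format(unclass(x), digits = 15, trim = TRUE)),
                     con, sep = sep, col.names = FALSE, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
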