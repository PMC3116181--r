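# Fixed label sets shared across the package. All descriptor bookkeeping
# (column order, group membership, class thresholds) is anchored here so
# coefficient/VIP indices are stable across runs and platforms.

#' Amino-acid codes used in composition matrices
#'
#' The 18 pooled amino-acid codes of acid-hydrolysis amino-acid analysis:
#' Asn and Asp are indistinguishable after hydrolysis and are pooled as
#' `ASX`; Glu and Gln likewise as `GLX`. The order is the canonical column
#' order of composition matrices and of the `AA` descriptor block.
#'
#' @format Character vector of length 18.
#' @export
aa_labels <- c("ASX", "THR", "SER", "GLX", "PRO", "GLY", "ALA", "CYS",
               "VAL", "MET", "ILE", "LEU", "TYR", "PHE", "HIS", "LYS",
               "ARG", "TRP")

#' Physicochemical amino-acid groups
#'
#' Membership of the five physicochemical groups used as the `gAA`
#' descriptor block: sulfur-containing (SCAA), positively charged (PCAA),
#' hydrophobic (HAA), acidic (AcAA) and aromatic (AAA) amino acids. The
#' list order is the canonical `gAA` column order.
#'
#' @format Named list of character vectors of [aa_labels] codes.
#' @export
aa_groups <- list(
  SCAA = c("CYS", "MET"),
  PCAA = c("ARG", "LYS", "HIS"),
  HAA  = c("PRO", "ALA", "CYS", "VAL", "MET", "ILE", "LEU", "TYR",
           "PHE", "TRP"),
  AcAA = c("ASX", "GLX"),
  AAA  = c("PHE", "TYR", "TRP")
)

# Column labels of the z-scale sum descriptor block.
zsum_labels <- c("sum_z1", "sum_z2", "sum_z3")

# Canonical descriptor set tokens. "all" is the combined 26-column block
# (18 AA + 5 gAA + 3 z sums); "AA+gAA+z" is accepted as a synonym.
x_set_tokens <- c("AA", "gAA", "z", "all")

normalize_x_set <- function(x_set) {
  stopifnot(is.character(x_set), length(x_set) == 1L)
  if (x_set %in% c("all", "AA+gAA+z", "combined")) return("all")
  if (x_set %in% x_set_tokens) return(x_set)
  stop("unknown x_set '", x_set, "'; expected one of ",
       paste(c(x_set_tokens, "AA+gAA+z"), collapse = ", "), call. = FALSE)
}
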