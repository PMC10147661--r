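#' Parts library for CRISPRi circuit genotypes
#'
#' A parts library fixes the mutational alphabet of the genotype space: the
#' ordered set of sgRNAs that can occupy an edge (repression) slot and the
#' ordered set of promoter efficiency levels available for the blue and green
#' nodes. The default library matches the experimentally characterised parts:
#' six sgRNAs (two of them 4-nt 5'-truncated, weaker variants marked `t4`) and
#' four promoter levels `PH`, `PM`, `PL`, `ZERO` with relative efficiencies
#' 1, 0.86, 0.75 and 0. The `ZERO` level models a promoter knockout; it is a
#' parameter value, not a topology change.
#'
#' @param sgrna_ids Character vector of unique sgRNA identifiers (edge alphabet).
#' @param promoters Named numeric vector of promoter efficiencies in `[0, 1]`;
#'   names are the promoter tokens used in the genotype encoding.
#' @return An object of class `grn_parts`: a list with elements `sgrna_ids`
#'   and `promoters`, plus counts `s` (sgRNAs) and `p` (promoter levels).
#' @examples
#' parts <- parts_library()
#' parts$s # 6
#' parts$p # 4
#' @export
parts_library <- function(sgrna_ids = c("sg1", "sg1t4", "sg2", "sg3", "sg4", "sg4t4"),
                          promoters = c(PH = 1, PM = 0.86, PL = 0.75, ZERO = 0)) {
  sgrna_ids <- as.character(sgrna_ids)
  if (anyDuplicated(sgrna_ids)) stop("sgRNA ids must be unique")
  if (is.null(names(promoters)) || anyDuplicated(names(promoters))) {
    stop("promoters must be a uniquely named numeric vector")
  }
  if (any(promoters < 0 | promoters > 1)) stop("promoter efficiencies must lie in [0, 1]")
  structure(
    list(
      sgrna_ids = sgrna_ids,
      promoters = promoters,
      s = length(sgrna_ids),
      p = length(promoters)
    ),
    class = "grn_parts"
  )
}

#' @export
print.grn_parts <- function(x, ...) {
  cat("<grn_parts> ", x$s, " sgRNAs: ", paste(x$sgrna_ids, collapse = ", "), "\n", sep = "")
  cat("  ", x$p, " promoter levels: ",
      paste(sprintf("%s=%g", names(x$promoters), x$promoters), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Artificial control-grid parts library
#'
#' A regular grid in parameter space used as a control for the fitted parts:
#' five promoter efficiencies evenly spaced on `[0, 1]` and five sgRNAs whose
#' dCas:sgRNA-to-DNA dissociation constants are evenly spaced from 5 to 45 nM.
#' The dissociation constants are carried as an attribute `kd_nM` so that a
#' matching parameter set can be derived with [make_truth()].
#'
#' @return A `grn_parts` object with 5 sgRNAs and 5 promoter levels.
#' @examples
#' grid_parts_library()$promoters
#' @export
grid_parts_library <- function() {
  parts <- parts_library(
    sgrna_ids = paste0("g", 1:5),
    promoters = c(E100 = 1, E75 = 0.75, E50 = 0.5, E25 = 0.25, ZERO = 0)
  )
  attr(parts, "kd_nM") <- seq(5, 45, length.out = 5)
  parts
}
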