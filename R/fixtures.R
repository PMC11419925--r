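#' Experimental melting temperatures of PcLiP01 variants
#'
#' The packaged panel of experimentally measured melting temperatures for
#' lignin peroxidase isozyme 1 of *Phanerochaete chrysosporium*: the wild
#' type, the single homology-guided mutants, the heme-contact double
#' mutant E40S/V181A, and two consensus-design (PROSS) variants. `aa181`
#' records the residue at the key heme-contacting position 181.
#'
#' @return data.frame with `variant`, `aa181`, `Tm_obs` (°C), `Tm_sd`.
#' @examples
#' p <- pclip_tm_panel()
#' tm_gain(p, "V181A")  # +5.01 over WT
#' @export
pclip_tm_panel <- function() {
  path <- system.file("extdata", "pclip01_tm_panel.csv",
                      package = "hemelock", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Melting-temperature gain of a variant over a reference
#'
#' @param panel data.frame with `variant` and `Tm_obs` columns.
#' @param variant variant label.
#' @param reference reference label (default wild type).
#' @return Tm(variant) - Tm(reference), °C.
#' @export
tm_gain <- function(panel, variant, reference = "WT") {
  lookup <- function(v) {
    row <- panel[panel$variant == v, , drop = FALSE]
    if (nrow(row) != 1L) stop("variant '", v, "' not found uniquely in panel")
    row$Tm_obs
  }
  lookup(variant) - lookup(reference)
}
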