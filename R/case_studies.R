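#' Reconstructed EMT case-study network
#'
#' The epithelial-to-mesenchymal transition (EMT) core: the SNAI1/ZEB1/ZEB2
#' transcription-factor axis repressing E-cadherin (CDH1), wired into
#' double-negative feedback with the miR-200, miR-203 and miR-34 families.
#' The edge list is reconstructed from published interaction tables (it is
#' a synthetic stand-in for the original supplementary file, which is not
#' redistributable as text); its summary statistics match the published
#' description of the network — 4 genes plus 3 miRNAs, 17 interactions of
#' which 2 activations and 15 inhibitions, 12 positive and 0 negative
#' elementary circuits — and it has exactly two attractors, the epithelial
#' state (CDH1 on, everything SNAI1/ZEB off, miRNAs on) and its
#' mesenchymal complement.
#'
#' @return `emt_network()` a `grn`; `emt_profiles()` the binarized
#'   epithelial (initial) / mesenchymal (final) profile pair for the four
#'   measured genes (miRNAs are unmeasured).
#' @examples
#' glance(emt_network())
#' @export
emt_network <- function() {
  read_grn(system.file("extdata", "emt_network_reconstructed.sif",
                       package = "reprodet"),
           dialect = "sif")
}

#' @rdname emt_network
#' @export
emt_profiles <- function() {
  read_profiles(system.file("extdata", "emt_profiles.tsv",
                            package = "reprodet"))
}

#' Bundled case-study networks
#'
#' Of the six published reprogramming case studies (T-helper, EMT, HL60,
#' iHEP, iCM, iPSC), only the EMT network can be assembled from material
#' printed in text form; the other five interaction lists live in a
#' supplementary data file that is not available here, so requesting them
#' is an informative error rather than a silent approximation.
#'
#' @param name one of `"emt"`, `"thelper"`, `"hl60"`, `"ihep"`, `"icm"`,
#'   `"ipsc"`.
#' @return a `grn` (for `"emt"`).
#' @export
case_study_network <- function(name = c("emt", "thelper", "hl60", "ihep",
                                        "icm", "ipsc")) {
  name <- match.arg(name)
  if (name == "emt") return(emt_network())
  stop("the full interaction list of the '", name, "' case-study network ",
       "is only distributed as a supplementary data file and is not ",
       "available in text form; only the EMT network could be ",
       "reconstructed from printed tables", call. = FALSE)
}
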