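#' The packaged synthetic OST-HTH architecture corpus
#'
#' Loads the architecture table shipped with the package
#' (`inst/extdata/osthth_architectures_synthetic.tsv`). This corpus is a
#' *synthetic reconstruction*, not a transcription of any published dataset:
#' the original OST-HTH architecture inventory lives in a figure and a
#' supplementary file that are not machine-readable, so the package ships a
#' stand-in built only from domain fusions described for the superfamily
#' (bacterial LK-nuclease+OST-HTH proteins, the Limkain b1-like eukaryotic
#' versions, Oskar's OST-HTH+SGNH fusion, the TDRD5/TDRD7-like Tudor
#' combinations, and the plant/ciliate/apicomplexan/stramenopile fusions to
#' RNA-binding, anchoring and ubiquitin-system domains).
#'
#' The corpus holds 59 records over 55 distinct architectures, 53 of which
#' contain the OST-HTH. Its composition is calibrated so that the
#' neighborhood-linkage profile of the OST-HTH at distance <= 2 under the
#' default category map reproduces the reported statistics for the real
#' corpus: 37/53 architectures RNA-binding-linked (70%), 31/53
#' anchoring-linked (58%), 13/53 Ub-system-linked (25%). Use it as a worked
#' example and consistency anchor, not as biological ground truth.
#'
#' @return An [arch_set()].
#' @examples
#' archs <- osthth_architectures()
#' linkage_profile(archs, "OST-HTH", default_category_map())
#' @export
osthth_architectures <- function() {
  read_architectures(system.file("extdata",
                                 "osthth_architectures_synthetic.tsv",
                                 package = "archnet", mustWork = TRUE))
}

#' The packaged default residue-class scheme
#'
#' Reads `inst/extdata/residue_classes.yaml`, which encodes the same scheme
#' as [residue_scheme()]'s defaults (h/l/s/p at threshold 0.7).
#'
#' @return A [residue_scheme()].
#' @export
default_residue_scheme <- function() {
  read_residue_scheme(system.file("extdata", "residue_classes.yaml",
                                  package = "archnet", mustWork = TRUE))
}
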