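#' Region labels for the default tau connectome model
#'
#' The default model operates on the 68 cortical regions of the
#' Desikan-Killiany (DK) atlas plus the bilateral hippocampus and amygdala,
#' giving 72 regions in total. Subcortical regions other than hippocampus and
#' amygdala are excluded because off-target tracer binding makes their tau
#' PET signal unreliable.
#'
#' @return Character vector of 72 region labels, left hemisphere
#'   (`lh_`-prefixed) followed by right hemisphere (`rh_`-prefixed).
#' @examples
#' length(tau_model_regions())
#' @export
tau_model_regions <- function() {
  base <- c(dk_cortical_parcels(), "hippocampus", "amygdala")
  c(paste0("lh_", base), paste0("rh_", base))
}

#' The 34 cortical parcel names of the Desikan-Killiany atlas (one hemisphere)
#'
#' @return Character vector of 34 parcel names without hemisphere prefix.
#' @export
dk_cortical_parcels <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
}

#' Default Braak-stage assignment for the DK-based region set
#'
#' Maps each of the 72 model regions to one of the six Braak stages of
#' stereotyped tau progression (entorhinal cortex first, then limbic regions,
#' basal temporal lobe, association cortex, and finally primary sensory
#' cortex). The assignment is an approximation built from the usual DK-atlas
#' Braak composites used in tau PET staging studies; any other named
#' stage mapping can be supplied to [braak_region_means()] instead.
#'
#' @param region_labels Character vector of region labels to map. Defaults to
#'   [tau_model_regions()].
#' @return Named integer vector (1-6) with one entry per region label.
#' @export
dk_braak_stages <- function(region_labels = tau_model_regions()) {
  stage_of <- c(
    entorhinal = 1L,
    hippocampus = 2L,
    amygdala = 3L, parahippocampal = 3L, fusiform = 3L, lingual = 3L,
    middletemporal = 4L, inferiortemporal = 4L, temporalpole = 4L,
    bankssts = 4L, insula = 4L, caudalanteriorcingulate = 4L,
    rostralanteriorcingulate = 4L, posteriorcingulate = 4L,
    isthmuscingulate = 4L,
    superiortemporal = 5L, transversetemporal = 5L, inferiorparietal = 5L,
    superiorparietal = 5L, supramarginal = 5L, precuneus = 5L,
    lateraloccipital = 5L, superiorfrontal = 5L, rostralmiddlefrontal = 5L,
    caudalmiddlefrontal = 5L, parsopercularis = 5L, parsorbitalis = 5L,
    parstriangularis = 5L, lateralorbitofrontal = 5L,
    medialorbitofrontal = 5L, frontalpole = 5L,
    precentral = 6L, postcentral = 6L, paracentral = 6L, cuneus = 6L,
    pericalcarine = 6L
  )
  parcel <- sub("^(lh|rh)_", "", region_labels)
  unknown <- setdiff(unique(parcel), names(stage_of))
  if (length(unknown) > 0) {
    stop("no Braak stage known for region(s): ", paste(unknown, collapse = ", "))
  }
  stats::setNames(stage_of[parcel], region_labels)
}

#' Constituent regions of the tau-positivity composites
#'
#' The medial temporal lobe (MTL) composite is the mean SUVR over the
#' bilateral entorhinal cortex and amygdala; the neocortical composite is the
#' mean over the bilateral middle and inferior temporal gyri.
#'
#' @return Character vector of region labels.
#' @export
mtl_composite_regions <- function() {
  c("lh_entorhinal", "rh_entorhinal", "lh_amygdala", "rh_amygdala")
}

#' @rdname mtl_composite_regions
#' @export
neocortical_composite_regions <- function() {
  c("lh_middletemporal", "rh_middletemporal",
    "lh_inferiortemporal", "rh_inferiortemporal")
}
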