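#' Desikan-Killiany cortical regions
#'
#' The 34 gyral-based cortical parcels of the Desikan-Killiany atlas, in
#' FreeSurfer's `aparc` spelling and order. Regional mean thickness tables are
#' normalised to this order on ingest, and every thickness profile handled by
#' the package carries exactly these 34 regions per hemisphere.
#'
#' @format Character vector of length 34.
#' @export
dk_regions <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula"
)
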