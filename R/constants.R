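#' OCT segmentation label schema
#'
#' Integer codes for the ten tissue/artefact classes used in multi-class OCT
#' plaque segmentation maps: background, guidewire artefact, lumen, intima,
#' media, lipid, calcium, side branch, plaque rupture and thrombus.
#'
#' @format Named integer vector of length 10 (codes 0--9).
#' @export
OCT_LABELS <- c(
  background = 0L, guidewire = 1L, lumen = 2L, intima = 3L, media = 4L,
  lipid = 5L, calcium = 6L, side_branch = 7L, plaque_rupture = 8L,
  thrombus = 9L
)

# guidewire-shadow rule: bins whose rays are dominated by guidewire pixels
# contribute no lipid evidence
GW_SHADOW_FRACTION <- 0.3
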