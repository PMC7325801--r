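#' Synthetic 360-parcel cortical atlas with planted MD membership
#'
#' Builds a bilateral atlas of 180 areas per hemisphere in the style of a
#' multimodal cortical parcellation. A fixed subset of areas carries
#' multiple-demand (MD) membership used as ground truth by the cohort
#' generator: 7 core areas strongly activated by all three task contrasts,
#' 3 core areas strongly activated by two of the three, and 17 penumbra
#' areas with weaker but consistent activation. MD and neighbouring areas
#' use their conventional names; the remaining parcels get systematic
#' placeholder names (`nm001`, ...).
#'
#' Network labels follow a canonical resting-state partition: all core MD
#' areas sit in the fronto-parietal network (FPN), penumbra areas are spread
#' over FPN, cingulo-opercular (CON), dorsal-attention (DAN) and default-mode
#' (DMN) networks, and non-MD parcels fill out the remaining networks.
#'
#' @return A data.frame with one row per parcel (360 rows) and columns
#'   `parcel` (hemisphere-qualified id, e.g. `"L_i6-8"`), `hemisphere`
#'   (`"L"`/`"R"`), `area` (hemisphere-free area name), `network`
#'   (resting-state network label) and `md_class` (one of `"core_full"`,
#'   `"core_partial"`, `"penumbra"`, `"background"`).
#' @export
#' @examples
#' atlas <- md_atlas()
#' table(atlas$md_class) / 2  # per-hemisphere counts
md_atlas <- function() {
  core_full <- c("i6-8", "p9-46v", "a9-46v", "8BM", "AVI", "IP1", "IP2")
  core_partial <- c("IFJp", "8C", "PFm")
  penumbra <- c("SCEF", "s6-8", "6r", "FOP5", "a47r", "p47r", "p10p",
                "a10p", "11l", "AIP", "LIPd", "MIP", "PGs", "POS2",
                "TE1m", "TE1p", "PF")
  # Non-MD areas with genuine but task-specific activation (fail the
  # three-contrast conjunction by construction).
  task_specific <- c("FEF", "PEF", "LIPv", "IFJa", "9-46d", "7Pm", "44", "55b")

  named <- c(core_full, core_partial, penumbra, task_specific)
  n_bg <- 180L - length(named)
  background <- sprintf("nm%03d", seq_len(n_bg))
  area <- c(named, background)

  md_class <- c(rep("core_full", length(core_full)),
                rep("core_partial", length(core_partial)),
                rep("penumbra", length(penumbra)),
                rep("background", length(task_specific) + n_bg))

  network <- rep(NA_character_, 180L)
  names(network) <- area
  network[c(core_full, core_partial)] <- "FPN"
  network[c("a47r", "p47r", "p10p", "a10p", "11l", "POS2", "TE1m",
            "TE1p", "PF")] <- "FPN"
  network[c("SCEF", "FOP5", "6r", "s6-8")] <- "CON"
  network[c("AIP", "LIPd", "MIP")] <- "DAN"
  network["PGs"] <- "DMN"
  network[c("FEF", "PEF", "LIPv")] <- "DAN"
  network[c("IFJa", "44", "55b")] <- "LAN"
  network["9-46d"] <- "CON"
  network["7Pm"] <- "DMN"
  # a few non-MD parcels inside the FPN (the canonical FPN is larger than
  # the MD core + penumbra)
  network[background[1:6]] <- "FPN"
  rest <- is.na(network)
  network[rest] <- rep(c("VIS1", "VIS2", "SMN", "AUD", "DMN", "CON", "DAN",
                         "PMM"),
                       length.out = sum(rest))

  one_hemi <- function(h) {
    data.frame(parcel = paste0(h, "_", area),
               hemisphere = h,
               area = area,
               network = unname(network),
               md_class = md_class,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_hemi("L"), one_hemi("R"))
  rownames(out) <- out$parcel
  out
}

#' Names of the 19 subcortical and cerebellar structures
#'
#' Standard whole-structure segmentation used for the subcortical analysis:
#' nine bilateral structures plus the brain stem.
#'
#' @return Character vector of length 19.
#' @export
md_structures <- function() {
  bilateral <- c("Caudate", "Putamen", "Pallidum", "Thalamus", "Cerebellum",
                 "Hippocampus", "Amygdala", "VentralDC", "Accumbens")
  c(paste0("L_", bilateral), paste0("R_", bilateral), "BrainStem")
}
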