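#' The cardiac substructure catalog
#'
#' Twenty cardiac substructures organised in four groups that are
#' mutually overlapping across groups but non-overlapping within a group:
#' A, the whole heart; B, the four chambers and five great vessels; C, the
#' four coronary arteries and four valves; D, the two conduction nodes.
#' Each group is segmented by its own decoder as an independent semantic
#' (single-label) problem, so a voxel may carry one label per group.
#'
#' @param groups Named list of character vectors, one per group, in decoder
#'   order. The default is the 20-structure cardiac catalog.
#' @return An object of class \code{structure_catalog}.
#' @export
structure_catalog <- function(groups = list(
  A = "WH",
  B = c("LA", "RA", "LV", "RV", "AA", "SVC", "IVC", "PA", "PVs"),
  C = c("RCA", "LMCA", "LADA", "LCFX", "V-AV", "V-PV", "V-MV", "V-TV"),
  D = c("N-SA", "N-AV"))) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  nm <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(nm))
    stop("structure names must be unique across the catalog")
  structure(list(groups = groups), class = "structure_catalog")
}

#' @export
print.structure_catalog <- function(x, ...) {
  cat("Structure catalog:", length(catalog_structures(x)), "structures in",
      length(x$groups), "groups\n")
  for (g in names(x$groups))
    cat(sprintf("  %s (%d): %s\n", g, length(x$groups[[g]]),
                paste(x$groups[[g]], collapse = ", ")))
  invisible(x)
}

#' All structure names of a catalog, in group order
#' @param catalog A \code{structure_catalog}.
#' @return Character vector of structure names.
#' @export
catalog_structures <- function(catalog) {
  unlist(catalog$groups, use.names = FALSE)
}

#' Group membership lookup
#' @param catalog A \code{structure_catalog}.
#' @param structure A structure name.
#' @return The id of the group containing \code{structure}.
#' @export
structure_group <- function(catalog, structure) {
  for (g in names(catalog$groups))
    if (structure %in% catalog$groups[[g]]) return(g)
  stop("unknown structure: ", structure)
}

#' Per-group class counts (structures + background)
#' @param catalog A \code{structure_catalog}.
#' @return Named integer vector, one entry per group.
#' @export
group_class_counts <- function(catalog) {
  vapply(catalog$groups, function(s) length(s) + 1L, integer(1))
}

#' Registered imaging modalities
#'
#' The default modality registry: radiotherapy simulation CT (\code{SIM_CT}),
#' low-field MR-Linac (\code{MR_LINAC}) and cardiac CT angiography
#' (\code{CCTA}). CT-like modalities (those producing values on a
#' Hounsfield-unit scale) are flagged so that intensity windowing is applied
#' only to them.
#'
#' @return Character vector of modality tags.
#' @export
magic_modalities <- function() c("SIM_CT", "MR_LINAC", "CCTA")

#' @rdname magic_modalities
#' @param modality A modality tag.
#' @return \code{ct_like} returns TRUE for modalities on an HU scale.
#' @export
ct_like <- function(modality) modality %in% c("SIM_CT", "CCTA")

# class of a structure for reporting (heart / chambers / GVs / CAs / valves
# / nodes)
structure_class <- function(structure) {
  if (structure == "WH") return("Heart")
  if (structure %in% c("LA", "RA", "LV", "RV")) return("Chambers")
  if (structure %in% c("AA", "SVC", "IVC", "PA", "PVs")) return("GVs")
  if (structure %in% c("RCA", "LMCA", "LADA", "LCFX")) return("CAs")
  if (structure %in% c("V-AV", "V-PV", "V-MV", "V-TV")) return("Valves")
  if (structure %in% c("N-SA", "N-AV")) return("Nodes")
  "Other"
}

#' Coronary-artery structure names (evaluated additionally with clDice)
#' @param catalog A \code{structure_catalog}.
#' @return Character vector.
#' @export
coronary_structures <- function(catalog = structure_catalog()) {
  s <- catalog_structures(catalog)
  s[vapply(s, structure_class, character(1)) == "CAs"]
}
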