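#' Dataset manifests
#'
#' A manifest is a plain CSV with columns \code{image}, \code{labels},
#' \code{modality}, \code{split} and \code{provenance}. Unlabeled entries
#' (for the pseudo-label round) leave \code{labels} empty and must sit in
#' the \code{unlabeled} split; every labeled entry points at a full-catalog
#' composite. \code{provenance} records whether a label is a manual contour
#' or a model-generated pseudo-label; pseudo entries are only ever used for
#' training.
#'
#' @param entries Data frame with the five manifest columns.
#' @param modalities Registered modality tags the manifest is validated
#'   against.
#' @return A validated \code{dataset_manifest} (a classed data frame).
#' @export
dataset_manifest <- function(entries, modalities = magic_modalities()) {
  need <- c("image", "labels", "modality", "split", "provenance")
  if (!all(need %in% names(entries)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  entries <- as.data.frame(entries)[need]
  for (col in need) entries[[col]] <- as.character(entries[[col]])
  entries$labels[is.na(entries$labels)] <- ""
  bad <- setdiff(unique(entries$modality), modalities)
  if (length(bad))
    stop("unknown modality in manifest: ", paste(bad, collapse = ", "),
         " (registered: ", paste(modalities, collapse = ", "), ")")
  ok_split <- c("train", "val", "test", "unlabeled")
  if (!all(entries$split %in% ok_split))
    stop("split must be one of: ", paste(ok_split, collapse = ", "))
  if (!all(entries$provenance %in% c("manual", "pseudo")))
    stop("provenance must be 'manual' or 'pseudo'")
  if (any(entries$split == "unlabeled" & nzchar(entries$labels)))
    stop("unlabeled entries must not carry a labels path")
  if (any(entries$split != "unlabeled" & !nzchar(entries$labels)))
    stop("labeled entries must carry a labels path")
  if (any(entries$split %in% c("val", "test") & entries$provenance == "pseudo"))
    stop("pseudo-labeled entries may only be used for training")
  class(entries) <- c("dataset_manifest", "data.frame")
  entries
}

#' @rdname dataset_manifest
#' @param path CSV path.
#' @param check_files If TRUE, verify that referenced files exist.
#' @export
load_manifest <- function(path, modalities = magic_modalities(),
                          check_files = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  m <- dataset_manifest(df, modalities)
  if (check_files) {
    miss <- m$image[!file.exists(m$image)]
    missl <- m$labels[nzchar(m$labels) & !file.exists(m$labels)]
    if (length(miss) || length(missl))
      stop("manifest references missing files: ",
           paste(c(miss, missl), collapse = ", "))
  }
  m
}

#' @rdname dataset_manifest
#' @param manifest A \code{dataset_manifest}.
#' @export
save_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  write.csv(as.data.frame(manifest), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("dataset manifest:", nrow(x), "entries\n")
  print(table(modality = x$modality, split = x$split))
  invisible(x)
}

manifest_subset <- function(manifest, split = NULL, modality = NULL) {
  keep <- rep(TRUE, nrow(manifest))
  if (!is.null(split)) keep <- keep & manifest$split %in% split
  if (!is.null(modality)) keep <- keep & manifest$modality %in% modality
  manifest[keep, , drop = FALSE]
}
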