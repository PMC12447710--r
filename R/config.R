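# YAML configuration round-trip for the cascade (backbone + modality
# registry + group catalog) and the training protocol.

#' Write / read a cascade specification as YAML
#'
#' The YAML file fully determines the architecture: backbone
#' hyperparameters, ordered modality list, and the ordered group catalog
#' (from which per-group class counts follow).
#'
#' @param spec A \code{\link{cascade_spec}}.
#' @param path YAML path.
#' @return \code{path} (write) / the \code{cascade_spec} (read).
#' @export
write_cascade_config <- function(spec, path) {
  obj <- list(backbone = unclass(spec$backbone),
              modalities = as.list(spec$modalities),
              groups = if (!is.null(spec$catalog))
                lapply(spec$catalog$groups, as.list)
              else as.list(spec$class_counts))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_cascade_config
#' @export
read_cascade_config <- function(path) {
  obj <- yaml::read_yaml(path)
  bs <- do.call(backbone_spec, obj$backbone)
  if (all(vapply(obj$groups, is.character, logical(1)))) {
    catalog <- structure_catalog(lapply(obj$groups, unlist))
    cascade_spec(bs, unlist(obj$modalities), group_class_counts(catalog),
                 catalog)
  } else {
    cascade_spec(bs, unlist(obj$modalities),
                 unlist(obj$groups), catalog = NULL)
  }
}

#' Write / read a training configuration as YAML
#' @param config A \code{\link{train_config}}.
#' @param path YAML path.
#' @return \code{path} (write) / the \code{train_config} (read).
#' @export
write_train_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_train_config
#' @export
read_train_config <- function(path) {
  do.call(train_config, yaml::read_yaml(path))
}
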