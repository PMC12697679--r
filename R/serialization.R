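# JSON serialization of fitted calibration models.  Finite numeric fields
# round-trip bit-exactly; the -Inf/+Inf histogram sentinels are encoded as
# the strings "-inf"/"+inf".

encode_edges <- function(edges) {
  out <- as.list(edges)
  out[[1]] <- "-inf"
  out[[length(out)]] <- "+inf"
  out
}

decode_edges <- function(lst) {
  v <- vapply(lst, function(e) {
    if (identical(e, "-inf")) -Inf
    else if (identical(e, "+inf")) Inf
    else as.numeric(e)
  }, numeric(1))
  v
}

node_to_list <- function(node) {
  out <- list(id = node$id,
              parent = node$parent,
              depth = node$depth,
              path = lapply(node$path, function(p) list(p$attr, p$value)),
              split_attr = node$split_attr,
              children = list(true = unname(node$children[["true"]]),
                              false = unname(node$children[["false"]])),
              n_total = node$n_total,
              n_pathogenic = node$n_pathogenic,
              n_benign = node$n_benign)
  if (!is.null(node$fraction)) {
    out$fraction <- node$fraction
    out$gmm_benign <- unclass(node$gmm_benign)
    out$gmm_pathogenic <- unclass(node$gmm_pathogenic)
    h <- node$histogram
    out$histogram <- list(edges = encode_edges(h$edges),
                          bin_fraction = h$bin_fraction,
                          bin_count = h$bin_count,
                          n_synthetic = h$n_synthetic)
  }
  out
}

list_to_node <- function(lst) {
  node <- list(id = lst$id,
               parent = lst$parent %||% NA_character_,
               depth = as.integer(lst$depth),
               path = lapply(lst$path, function(p) {
                 list(attr = p[[1]], value = as.logical(p[[2]]))
               }),
               members = integer(0),
               available = character(0),
               split_attr = lst$split_attr %||% NA_character_,
               children = c("true" = lst$children$true %||% NA_character_,
                            "false" = lst$children$false %||% NA_character_),
               n_total = as.integer(lst$n_total),
               n_pathogenic = as.integer(lst$n_pathogenic),
               n_benign = as.integer(lst$n_benign),
               fraction = NULL, gmm_benign = NULL, gmm_pathogenic = NULL,
               histogram = NULL)
  if (!is.null(lst$fraction)) {
    node$fraction <- as.numeric(lst$fraction)
    node$gmm_benign <- gmm_params(unlist(lst$gmm_benign$weights),
                                  unlist(lst$gmm_benign$means),
                                  unlist(lst$gmm_benign$variances))
    node$gmm_pathogenic <- gmm_params(unlist(lst$gmm_pathogenic$weights),
                                      unlist(lst$gmm_pathogenic$means),
                                      unlist(lst$gmm_pathogenic$variances))
    node$histogram <- structure(
      list(edges = decode_edges(lst$histogram$edges),
           bin_fraction = as.numeric(unlist(lst$histogram$bin_fraction)),
           bin_count = as.integer(unlist(lst$histogram$bin_count)),
           n_synthetic = as.integer(lst$histogram$n_synthetic)),
      class = "calibration_histogram")
  }
  node
}

#' Serialize a calibration model to JSON
#'
#' @param model a fitted \code{calib_model}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_calib_model <- function(model, path) {
  payload <- list(version = model$version,
                  kind = "racoon_tree",
                  config = unclass(model$config),
                  attribute_names = model$attribute_names,
                  nodes = unname(lapply(model$tree$nodes, node_to_list)))
  # I(17) significant digits: doubles survive the JSON round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' @param path path to a model file written by \code{\link{write_calib_model}}.
#' @return a \code{calib_model} usable for prediction.
#' @export
read_calib_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$kind, "racoon_tree")) {
    stop("not a calibration-tree model file")
  }
  cfg <- payload$config
  cfg$partition_attrs <- unlist(cfg$partition_attrs)
  cfg <- structure(cfg, class = "tree_config")
  nodes <- lapply(payload$nodes, list_to_node)
  names(nodes) <- vapply(nodes, `[[`, character(1), "id")
  tree <- structure(list(nodes = nodes, root = "root", cfg = cfg),
                    class = "calib_tree")
  structure(list(version = payload$version, config = cfg, tree = tree,
                 attribute_names = unlist(payload$attribute_names),
                 fitted_at = NULL),
            class = "calib_model")
}
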