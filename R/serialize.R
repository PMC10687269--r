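# JSON containers for graph bundles and model checkpoints. Edges are stored
# 0-based, undirected edges once; matrices are stored with explicit dims so
# round-trips are exact.

mat_to_json <- function(m) {
  list(dim = dim(m) %||% c(length(m), 1L), data = as.numeric(m))
}

mat_from_json <- function(x) {
  matrix(unlist(x$data), nrow = x$dim[[1]], ncol = x$dim[[2]])
}

protein_graph_to_list <- function(g) {
  list(
    protein_id = g$protein_id,
    n_residues = g$n_residues,
    cutoff = g$cutoff,
    coords = mat_to_json(g$coords),
    node_features = mat_to_json(g$node_features),
    edges = list(i = g$edges$i, j = g$edges$j, distance = g$edges$distance)
  )
}

protein_graph_from_list <- function(x) {
  build_protein_graph(
    mat_from_json(x$coords), mat_from_json(x$node_features),
    x$protein_id, cutoff = x$cutoff
  )
}

molecule_graph_to_list <- function(g) {
  list(
    molecule_id = g$molecule_id,
    smiles = g$smiles,
    n_atoms = g$n_atoms,
    node_features = mat_to_json(g$node_features),
    edges = lapply(as.list(g$edges), as.integer)
  )
}

molecule_graph_from_list <- function(x) {
  nf <- mat_from_json(x$node_features)
  storage.mode(nf) <- "integer"
  colnames(nf) <- names(feature_vocab_sizes()$atom)
  ed <- tibble::as_tibble(lapply(x$edges, function(col) as.integer(unlist(col))))
  if (nrow(ed) == 0L) {
    ed <- tibble::tibble(i = integer(), j = integer(), bond_type = integer(),
                         stereo = integer(), conjugated = integer())
  }
  new_molecule_graph(x$molecule_id, x$smiles %||% NA_character_, nf, ed)
}

#' Write a graph bundle to JSON
#'
#' @param proteins list of `protein_graph`
#' @param molecules list of `molecule_graph`
#' @param path output file
#' @export
write_graph_bundle <- function(proteins, molecules, path) {
  bundle <- list(
    format = "metabind_graph_bundle",
    version = 1L,
    proteins = lapply(proteins, protein_graph_to_list),
    molecules = lapply(molecules, molecule_graph_to_list)
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a graph bundle written by [write_graph_bundle()]
#' @param path JSON file
#' @return list with `proteins` and `molecules`
#' @export
read_graph_bundle <- function(path) {
  x <- jsonlite::read_json(path)
  if (!identical(x$format, "metabind_graph_bundle")) {
    stop_parse("not a metabind graph bundle")
  }
  list(
    proteins = lapply(x$proteins, protein_graph_from_list),
    molecules = lapply(x$molecules, molecule_graph_from_list)
  )
}

#' Save a meta-model checkpoint to JSON
#'
#' All named parameter groups (protein/molecule encoders, assignment MLP,
#' critic, classifier, attention, per-layer per-step learning rates) plus the
#' model configuration, version-stamped.
#'
#' @param model a `metabind_model`
#' @param path output file
#' @export
save_checkpoint <- function(model, path) {
  ser <- function(p) {
    if (is_param_leaf(p)) return(mat_to_json(as.matrix(p)))
    lapply(p, ser)
  }
  obj <- list(
    format = "metabind_checkpoint", version = 1L,
    config = list(base = unclass(model$config$base),
                  meta = unclass(model$config$meta)),
    params = ser(model$params)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path JSON file
#' @return a `metabind_model`
#' @export
load_checkpoint <- function(path) {
  x <- jsonlite::read_json(path)
  if (!identical(x$format, "metabind_checkpoint")) {
    stop_parse("not a metabind checkpoint")
  }
  deser <- function(p) {
    if (!is.null(p$dim) && !is.null(p$data)) return(mat_from_json(p))
    lapply(p, deser)
  }
  clean <- function(lst) {
    lst <- lst[!vapply(lst, is.null, TRUE)]
    lapply(lst, function(v) if (is.list(v)) unlist(v) else v)
  }
  base_cfg <- do.call(base_config, clean(x$config$base))
  meta_args <- clean(x$config$meta)
  meta_cfg <- do.call(meta_config,
                      meta_args[names(meta_args) %in% names(formals(meta_config))])
  params <- deser(x$params)
  # restore exact leaf shapes (vectors vs matrices) from a config template
  tmpl <- withr::with_seed(1L, init_meta_params(base_cfg, meta_cfg))
  params <- par_map2(params, tmpl, function(loaded, t) {
    if (is.matrix(t)) {
      m <- matrix(as.numeric(loaded), nrow(t), ncol(t))
      dimnames(m) <- dimnames(t)
      m
    } else {
      setNames(as.numeric(loaded), names(t))
    }
  })
  structure(
    list(params = params, config = list(base = base_cfg, meta = meta_cfg),
         trace = NULL),
    class = "metabind_model"
  )
}
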