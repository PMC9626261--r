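# versioned plain-text artifact formats: CSV for style matrices, JSON for
# models and parameter trajectories

STYLE_SCHEMA <- "styledyn_style_matrix_v1"
MODEL_SCHEMA <- "styledyn_mixture_v1"
TRAJ_SCHEMA <- "styledyn_trajectory_v1"

#' Read and write styledyn artifacts
#'
#' Plain-text, versioned persistence for the package's objects: style tables
#' as CSV with a schema comment line, mixtures and parameter trajectories as
#' JSON. `read_*(write_*(x))` reproduces `x` to full double precision.
#'
#' @param styles,model,trajectory Object to write.
#' @param path File path.
#' @return The written path (invisibly) for writers; the reconstructed
#'   object for readers.
#' @name styledyn_io
NULL

#' @rdname styledyn_io
#' @export
write_style_table <- function(styles, path) {
  header <- sprintf("#%s kind=%s", STYLE_SCHEMA, style_feature_kind(styles))
  writeLines(header, path)
  readr::write_csv(as_tibble(as.data.frame(styles)), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname styledyn_io
#' @export
read_style_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, paste0("#", STYLE_SCHEMA)))
    abort(sprintf("%s is not a %s file (schema line missing or mismatched)", path, STYLE_SCHEMA))
  kind <- sub(".*kind=", "", first)
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!all(style_meta_cols %in% names(out)))
    abort(sprintf("%s is missing style metadata columns", path))
  out <- out %>% mutate(song_id = as.character(.data$song_id),
                        year = as.integer(.data$year))
  attr(out, "feature_kind") <- kind
  class(out) <- c("style_tbl", class(out))
  out
}

#' @rdname styledyn_io
#' @export
write_style_mixture <- function(model, path) {
  obj <- list(schema = MODEL_SCHEMA, K = model$K, weights = model$weights,
              component_probs = model$component_probs,
              loglik = model$loglik, n = model$n,
              feature_names = model$feature_names)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

parse_json <- function(path, schema, simplify = TRUE) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = simplify),
                  error = function(e)
                    abort(sprintf("failed to parse %s: %s", path, conditionMessage(e))))
  if (!identical(obj$schema, schema))
    abort(sprintf("%s has schema '%s'; expected '%s' (no migration available)",
                  path, obj$schema %||% "<none>", schema))
  obj
}

#' @rdname styledyn_io
#' @export
read_style_mixture <- function(path) {
  obj <- parse_json(path, MODEL_SCHEMA)
  p <- matrix(unlist(obj$component_probs), nrow = obj$K)
  colnames(p) <- obj$feature_names
  structure(list(K = as.integer(obj$K), weights = as.numeric(obj$weights),
                 component_probs = p, loglik = obj$loglik,
                 loglik_trace = obj$loglik, n = as.integer(obj$n),
                 feature_names = obj$feature_names),
            class = "style_mixture")
}

#' @rdname styledyn_io
#' @export
write_dmm_trajectory <- function(trajectory, path) {
  recs <- lapply(unclass(trajectory), function(p)
    list(t = p$t, pi = p$pi, alpha = p$alpha, mu = p$mu))
  obj <- list(schema = TRAJ_SCHEMA,
              feature_names = colnames(trajectory[[1]]$mu),
              params = unname(recs))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname styledyn_io
#' @export
read_dmm_trajectory <- function(path) {
  obj <- parse_json(path, TRAJ_SCHEMA, simplify = FALSE)
  feat <- unlist(obj$feature_names)
  getp <- function(r) {
    mu <- do.call(rbind, lapply(r$mu, unlist))
    colnames(mu) <- feat
    dmm_params(r$t[[1]], unlist(r$pi), unlist(r$alpha), mu)
  }
  new_dmm_trajectory(lapply(obj$params, getp))
}
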