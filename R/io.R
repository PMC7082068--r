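#' Read a reaction network from a YAML file
#'
#' The canonical network schema is a YAML mapping with keys `species`
#' (list), `reactions` (list of mappings with `reactants`, `products`,
#' `modifiers`, `param`, optional `module`; species-to-stoichiometry maps
#' or plain lists for unit stoichiometry), `initial_state` (species-value
#' map) and optional `inputs` (list of `{name, value, start, end}`
#' windows). Fixture networks for the shipped benchmarks are installed
#' under `system.file("extdata", package = "ptlasso")`.
#'
#' @param path YAML file path.
#' @return a [reaction_network()].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  need <- c("species", "reactions")
  if (!all(need %in% names(y)))
    stop("network file needs keys: ", paste(need, collapse = ", "))
  rxns <- lapply(y$reactions, function(r) {
    reaction(reactants = side_from_yaml(r$reactants),
             products = side_from_yaml(r$products),
             param = r$param,
             modifiers = as.character(unlist(r$modifiers)),
             module = if (is.null(r$module)) NA_character_ else r$module)
  })
  inputs <- if (!is.null(y$inputs))
    do.call(rbind, lapply(y$inputs, as.data.frame))
  reaction_network(as.character(unlist(y$species)), rxns,
                   initial_state = unlist(y$initial_state),
                   inputs = inputs)
}

side_from_yaml <- function(x) {
  if (is.null(x) || !length(x)) return(character())
  if (is.list(x) && !is.null(names(x))) return(unlist(x))
  if (!is.null(names(x))) return(x)
  as.character(unlist(x))
}

#' Write a reaction network to YAML
#'
#' @param network a [reaction_network()].
#' @param path output path.
#' @export
write_network <- function(network, path) {
  y <- list(
    species = as.list(network$species),
    reactions = lapply(network$reactions, function(r) {
      out <- list(reactants = as.list(r$reactants),
                  products = as.list(r$products),
                  param = r$param)
      if (length(r$modifiers)) out$modifiers <- as.list(r$modifiers)
      if (!is.na(r$module)) out$module <- r$module
      out
    }),
    initial_state = as.list(
      network$initial_state[network$initial_state != 0]))
  if (!is.null(network$inputs))
    y$inputs <- lapply(seq_len(nrow(network$inputs)), function(i)
      as.list(network$inputs[i, ]))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write an observed dataset as TSV with a provenance sidecar
#'
#' The data go to `path` as tidy TSV (experiment, species, time, mean, sd)
#' and the generator provenance to `paste0(path, ".json")`, so the dataset
#' can be regenerated exactly via [regenerate_observed()].
#'
#' @param obs an `"observed_data"` data.frame.
#' @param path output TSV path.
#' @export
write_observed <- function(obs, path) {
  utils::write.table(as.data.frame(obs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prov <- attr(obs, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an observed dataset written by [write_observed()]
#'
#' @param path TSV path; the `.json` sidecar is attached as provenance if
#'   present.
#' @return an `"observed_data"` data.frame.
#' @export
read_observed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obs <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = list(experiment = "character"))
  side <- paste0(path, ".json")
  prov <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
  structure(obs, class = c("observed_data", "data.frame"),
            provenance = prov)
}

#' Write a sample store as tidy TSV
#'
#' One row per (swap, chain): columns swap, chain, beta, phase
#' (burn-in/sampling), energy, then one column per sampled parameter
#' (log10 values). This TSV is the canonical interchange format consumed
#' by the diagnose/reduce command-line tools.
#'
#' @param run a `"pt_run"` or `"ptlasso_fit"`.
#' @param path output path.
#' @param chains chain indices to write (default: all).
#' @return the path, invisibly.
#' @export
write_samples <- function(run, path, chains = NULL) {
  if (inherits(run, "ptlasso_fit")) run <- run$run
  stopifnot(inherits(run, "pt_run"))
  d <- dim(run$theta)
  if (is.null(chains)) chains <- seq_len(d[2])
  rows <- lapply(chains, function(c_i) {
    th <- matrix(run$theta[, c_i, ], nrow = d[1])
    colnames(th) <- run$par_names
    data.frame(swap = seq_len(d[1]), chain = c_i, beta = run$betas[c_i],
               phase = ifelse(seq_len(d[1]) <= run$burn_in, "burn-in",
                              "sampling"),
               energy = run$energy[, c_i], th, check.names = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample store TSV
#'
#' @param path TSV from [write_samples()].
#' @return data.frame with the store columns.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

store_posterior <- function(store) {
  # beta = 1 sampling-phase parameter matrix from a sample-store data.frame
  keep <- store$chain == 1 & store$phase == "sampling"
  drop <- c("swap", "chain", "beta", "phase", "energy")
  as.matrix(store[keep, setdiff(names(store), drop), drop = FALSE])
}
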