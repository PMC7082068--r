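#' Define a single mass-action reaction
#'
#' A reaction converts reactant species into product species at a rate equal
#' to the rate constant times the product of the reactant abundances (raised
#' to their stoichiometries) and the abundances of any modifiers. Modifiers
#' affect the rate without being consumed, which is how catalytic influences
#' are represented. Reactions with no reactants (optionally with modifiers)
#' model zero-order or catalyzed synthesis; reactions with no products model
#' degradation.
#'
#' @param reactants named integer vector of consumed species (values are
#'   stoichiometric coefficients), or a character vector for unit
#'   stoichiometry. May be empty.
#' @param products named integer vector (or character vector) of produced
#'   species. May be empty.
#' @param param name of the rate-constant parameter. First-order rate
#'   constants carry units s^-1, second-order molecule^-1 s^-1.
#' @param modifiers character vector of species that multiply the rate
#'   without being consumed.
#' @param module optional module label used by the grouped penalty.
#' @return an object of class `"reaction"`.
#' @seealso [reaction_network()]
#' @export
reaction <- function(reactants, products, param, modifiers = character(),
                     module = NA_character_) {
  reactants <- as_stoich(reactants, "reactants")
  products <- as_stoich(products, "products")
  if (!is.character(param) || length(param) != 1L || !nzchar(param))
    stop("'param' must be a single non-empty parameter name")
  if (!is.character(modifiers))
    stop("'modifiers' must be a character vector of species names")
  structure(
    list(reactants = reactants, products = products,
         modifiers = as.character(modifiers), param = param,
         module = as.character(module)),
    class = "reaction")
}

# normalize stoichiometry input to a named integer vector
as_stoich <- function(x, what) {
  if (is.null(x) || length(x) == 0L) return(integer(0))
  if (is.character(x)) x <- stats::setNames(rep(1L, length(x)), x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(sprintf("'%s' must be named by species", what))
  if (any(x != as.integer(x)) || any(x < 1))
    stop(sprintf("stoichiometric coefficients in '%s' must be positive integers",
                 what))
  stats::setNames(as.integer(x), names(x))
}

#' Construct a mass-action reaction network
#'
#' The network holds an ordered species list, a set of mass-action reactions,
#' initial abundances (molecules), and an optional piecewise-constant stimulus
#' schedule. Species named in the schedule are treated as externally clamped
#' inputs during simulation: their value is set by the schedule (0 outside the
#' scheduled windows) and they are not integrated.
#'
#' @param species character vector of species names (order defines the state
#'   vector).
#' @param reactions list of [reaction()] objects. Rate-parameter names must be
#'   unique across reactions.
#' @param initial_state named numeric vector of non-negative initial
#'   abundances; species not named start at 0.
#' @param inputs optional stimulus schedule: a data.frame with columns
#'   `name` (an input species), `value`, `start`, `end` (seconds), applied as
#'   a piecewise-constant clamp.
#' @return an object of class `"reaction_network"`.
#' @examples
#' net <- reaction_network(
#'   species = c("A", "B"),
#'   reactions = list(reaction("A", "B", param = "k_AB")),
#'   initial_state = c(A = 100))
#' net
#' @export
reaction_network <- function(species, reactions, initial_state = numeric(),
                             inputs = NULL) {
  if (!is.character(species) || length(species) < 1L ||
      anyDuplicated(species))
    stop("'species' must be a character vector of unique names")
  if (!is.list(reactions) ||
      !all(vapply(reactions, inherits, logical(1), "reaction")))
    stop("'reactions' must be a list of reaction() objects")
  referenced <- unlist(lapply(reactions, function(r)
    c(names(r$reactants), names(r$products), r$modifiers)))
  unknown <- setdiff(referenced, species)
  if (length(unknown))
    stop("reaction references unknown species: ", paste(unknown, collapse = ", "))
  pars <- vapply(reactions, `[[`, character(1), "param")
  if (anyDuplicated(pars))
    stop("rate-parameter names must be unique across reactions; duplicated: ",
         paste(unique(pars[duplicated(pars)]), collapse = ", "))
  x0 <- stats::setNames(numeric(length(species)), species)
  if (length(initial_state)) {
    if (is.null(names(initial_state)) ||
        !all(names(initial_state) %in% species))
      stop("'initial_state' must be named by known species")
    if (any(initial_state < 0))
      stop("initial abundances must be >= 0")
    x0[names(initial_state)] <- initial_state
  }
  inputs <- validate_schedule(inputs, species)
  mods <- vapply(reactions, `[[`, character(1), "module")
  if (any(!is.na(mods)) && any(is.na(mods)))
    stop("either every reaction carries a module label or none does")
  structure(
    list(species = species, reactions = reactions, initial_state = x0,
         inputs = inputs),
    class = "reaction_network")
}

validate_schedule <- function(inputs, species) {
  if (is.null(inputs) || (is.data.frame(inputs) && nrow(inputs) == 0L))
    return(NULL)
  inputs <- as.data.frame(inputs)
  need <- c("name", "value", "start", "end")
  if (!all(need %in% names(inputs)))
    stop("stimulus schedule needs columns: ", paste(need, collapse = ", "))
  if (!all(inputs$name %in% species))
    stop("stimulus schedule names unknown species: ",
         paste(setdiff(inputs$name, species), collapse = ", "))
  if (any(inputs$end <= inputs$start))
    stop("stimulus windows must have end > start")
  inputs[need]
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Mass-action reaction network: %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  cat("Species:", paste(x$species, collapse = ", "), "\n")
  mods <- network_modules(x)
  for (r in x$reactions) {
    lhs <- fmt_side(r$reactants)
    rhs <- fmt_side(r$products)
    mod <- if (length(r$modifiers))
      paste0(" [", paste(r$modifiers, collapse = ","), "]") else ""
    grp <- if (!is.na(r$module)) paste0("  (module: ", r$module, ")") else ""
    cat(sprintf("  %s -> %s%s  @ %s%s\n", lhs, rhs, mod, r$param, grp))
  }
  if (!is.null(x$inputs)) {
    cat("Inputs:\n")
    for (i in seq_len(nrow(x$inputs)))
      cat(sprintf("  %s = %g on [%g, %g) s\n", x$inputs$name[i],
                  x$inputs$value[i], x$inputs$start[i], x$inputs$end[i]))
  }
  invisible(x)
}

fmt_side <- function(st) {
  if (!length(st)) return("0")
  paste(ifelse(st > 1L, paste0(st, " ", names(st)), names(st)), collapse = " + ")
}

#' Rate-parameter names of a network
#'
#' @param network a [reaction_network()].
#' @return character vector of parameter names in reaction order.
#' @export
network_params <- function(network) {
  vapply(network$reactions, `[[`, character(1), "param")
}

#' Module labels of a network
#'
#' @param network a [reaction_network()].
#' @return named character vector mapping each rate parameter to its module
#'   label, or `NULL` for unlabelled networks.
#' @export
network_modules <- function(network) {
  mods <- vapply(network$reactions, `[[`, character(1), "module")
  if (all(is.na(mods))) return(NULL)
  stats::setNames(mods, network_params(network))
}

#' Complete directed network of first-order conversions
#'
#' Builds the fully connected n-node network of unimolecular conversion
#' reactions: one reaction per ordered pair of species, so n(n-1) reactions
#' in total (6 for n = 3, 20 for n = 5). Species are named A, B, C, ...;
#' the system starts with 100 molecules of A and all other species at 0.
#' Fitting this dense prior network to data generated from a sparse motif
#' (such as the A -> B -> C pulse generator) is the benchmark setting for
#' Lasso-based reaction elimination.
#'
#' @param n node count (>= 2).
#' @param a0 initial abundance of species A (molecules); default 100.
#' @return a [reaction_network()] with parameters named `k_XY` for the
#'   conversion X -> Y.
#' @examples
#' complete_unimolecular_network(3)
#' @export
complete_unimolecular_network <- function(n, a0 = 100) {
  if (!is.numeric(n) || length(n) != 1L || n != as.integer(n) || n < 2)
    stop("invalid network: node count 'n' must be an integer >= 2")
  sp <- LETTERS[seq_len(n)]
  rxns <- list()
  for (from in sp) for (to in sp) {
    if (from == to) next
    rxns[[length(rxns) + 1L]] <-
      reaction(from, to, param = paste0("k_", from, to))
  }
  reaction_network(sp, rxns, initial_state = c(A = a0))
}

#' Combined linear + perfectly-adapting dose-response network
#'
#' The prior network over a clamped signal S, observed response R and hidden
#' intermediate X that superimposes the two classic Tyson dose-response
#' motifs. The linear motif is S-driven production of R (`k_srs`, rate
#' k*S) with first-order decay (`k_r0`); at steady state R* =
#' (k_srs/k_r0) * S, linear in S. The adaptive (sniffer) motif adds S-driven
#' production of X (`k_sxs`), X decay (`k_x0`) and X-catalyzed removal of R
#' (`k_xrx`, rate k*X*R); its steady state R* = k_srs*k_x0/(k_xrx*k_sxs) is
#' independent of S (perfect adaptation). The sixth reaction, basal
#' signal-independent production of R (`k_0r`), completes the
#' six-parameter prior; the basal synthesis term of the linear motif is the
#' natural sixth reaction, and this completion is the package's
#' reconstruction (flagged as such in the shipped fixture file).
#'
#' @return a [reaction_network()] with species S (input), R, X and parameters
#'   k_0r, k_srs, k_r0, k_sxs, k_x0, k_xrx.
#' @export
dose_response_network <- function() {
  reaction_network(
    species = c("S", "R", "X"),
    reactions = list(
      reaction(character(), "R", param = "k_0r"),
      reaction(character(), "R", param = "k_srs", modifiers = "S"),
      reaction("R", character(), param = "k_r0"),
      reaction(character(), "X", param = "k_sxs", modifiers = "S"),
      reaction("X", character(), param = "k_x0"),
      reaction("R", character(), param = "k_xrx", modifiers = "X")))
}

#' Synthetic modular signalling toy network
#'
#' A small receptor-style network partitioned into three labelled reaction
#' modules, built as a desk-scale fixture for the grouped penalty. An input
#' signal S activates a transducer (I -> A, deactivating back A -> I: the
#' "activation" module); active transducer drives production of an observed
#' response R with first-order decay (the "output" module); and A slowly
#' accumulates a feedback species F which catalyzes deactivation of A (the
#' "feedback" module). The rates are chosen so that under a short input pulse
#' the feedback module is numerically dispensable (F never accumulates), while
#' under continuous stimulation the feedback is required to reproduce the
#' adapting response. The topology and rate values are a synthetic artifact
#' of this package, not a published model.
#'
#' @return a [reaction_network()] with module labels "activation", "output"
#'   and "feedback".
#' @seealso [modular_toy_truth()] for the generative rate constants.
#' @export
modular_toy_network <- function() {
  reaction_network(
    species = c("S", "I", "A", "R", "F"),
    reactions = list(
      reaction("I", "A", param = "k_act", modifiers = "S",
               module = "activation"),
      reaction("A", "I", param = "k_deact", module = "activation"),
      reaction(character(), "R", param = "k_prod", modifiers = "A",
               module = "output"),
      reaction("R", character(), param = "k_dec", module = "output"),
      reaction(character(), "F", param = "k_fprod", modifiers = "A",
               module = "feedback"),
      reaction("A", "I", param = "k_fb", modifiers = "F",
               module = "feedback"),
      reaction("F", character(), param = "k_fdec", module = "feedback")),
    initial_state = c(I = 100))
}

#' Generative rate constants for the modular toy network
#'
#' @return named numeric vector of the synthetic true rate constants used to
#'   generate modular-toy benchmark data.
#' @export
modular_toy_truth <- function() {
  c(k_act = 0.5, k_deact = 0.3, k_prod = 0.2, k_dec = 0.2,
    k_fprod = 0.005, k_fb = 0.5, k_fdec = 0.01)
}

#' Stimulus schedules for the modular toy network
#'
#' Protocol `"pulse"` applies S = 1 for the first 0.25 seconds only, with
#' the response observed over (0, 4] s; protocol `"continuous"` applies
#' S = 1 over the whole 60-second window, with observation times placed on
#' the rise, the peak and the slow adapting decline of the response. The
#' feedback module is dispensable under the pulse protocol (too little
#' feedback species accumulates to alter the response within the noise
#' level) and required under the continuous one: the observed
#' rise-peak-decline shape cannot be produced by the monotone
#' feedback-free model.
#'
#' @param protocol `"pulse"` or `"continuous"`.
#' @return a stimulus-schedule data.frame for [simulate_network()].
#' @export
modular_toy_protocol <- function(protocol = c("pulse", "continuous")) {
  protocol <- match.arg(protocol)
  if (protocol == "pulse")
    data.frame(name = "S", value = 1, start = 0, end = 0.25)
  else
    data.frame(name = "S", value = 1, start = 0, end = 60)
}

#' Observation time grid for a modular toy protocol
#'
#' Eight time points per protocol, excluding t = 0 where the response is
#' identically zero: evenly spaced over (0, 4] s for the pulse, and placed
#' across the rise, peak and adapting decline for the continuous protocol.
#'
#' @inheritParams modular_toy_protocol
#' @return numeric vector of 8 observation times (s).
#' @export
modular_toy_observation_times <- function(protocol = c("pulse", "continuous")) {
  protocol <- match.arg(protocol)
  if (protocol == "pulse") seq(0.5, 4, length.out = 8)
  else c(1, 2.5, 5, 10, 20, 30, 45, 60)
}
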