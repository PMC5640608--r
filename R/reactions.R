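#' Stoichiometric reaction
#'
#' A named metabolic step summarised as the `carrier_ledger` it leaves behind
#' per unit flux, together with the number of electrons the non-carrier
#' species donate to (positive) or accept from (negative) the carrier pool.
#' The declared electron count guards against transcription errors: for a
#' redox-balanced reaction, `2 * (fd_rd_pairs + nadh + nadph)` must equal it.
#'
#' @param name unique identifier within a reaction set.
#' @param ledger a `carrier_ledger` (or named numeric coercible to one).
#' @param reversible may the step carry negative flux in a pathway?
#' @param electrons declared electron count. For a redox reaction, the signed
#'   electrons its non-carrier species donate to the carrier pool; for a pure
#'   carrier interconversion (Rnf, Nfn), the gross electrons moved through
#'   the enzyme (its carriers must net to zero).
#' @param interconversion is this a pure carrier interconversion?
#' @return An object of class `reaction`.
#' @examples
#' # Nfn: four electrons from one NADH and two Fd_rd to two NADP
#' reaction("nfn", carrier_ledger(fd_rd_pairs = -1, nadh = -1, nadph = 2),
#'          reversible = TRUE, electrons = 4, interconversion = TRUE)
#' @export
reaction <- function(name, ledger, reversible = FALSE, electrons = 0,
                     interconversion = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, ledger = as_ledger(ledger),
                 reversible = isTRUE(reversible), electrons = electrons,
                 interconversion = isTRUE(interconversion)),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  cat(sprintf("<reaction> %s%s (electrons %+g)\n", x$name,
              if (x$reversible) " [reversible]" else "", x$electrons))
  print(x$ledger)
  invisible(x)
}

#' Check electron conservation of a reaction
#'
#' Report-only balance check guarding transcription errors. For a redox
#' reaction, electrons gained by the carrier pool (2 per unit of Fd_rd pair,
#' NADH or NADPH) must equal the electrons the reaction declares its
#' non-carrier species donate. For a pure carrier interconversion (Rnf, Nfn),
#' the carriers must net to zero electrons while the declaration records the
#' gross electrons moved.
#'
#' @param rxn a `reaction`.
#' @return A list with elements `name`, `carrier_electrons`,
#'   `declared_electrons`, and logical `balanced`.
#' @export
check_balance <- function(rxn) {
  stopifnot(inherits(rxn, "reaction"))
  ce <- carrier_electrons(rxn$ledger)
  balanced <- if (rxn$interconversion) abs(ce) < 1e-9
              else abs(ce - rxn$electrons) < 1e-9
  list(name = rxn$name, carrier_electrons = ce,
       declared_electrons = rxn$electrons, balanced = balanced)
}

#' Parse a reaction set from structured text
#'
#' Reads the YAML reaction definitions shipped with the package (or supplied
#' by the user) into a named list of [reaction()] objects. Each entry maps a
#' reaction name to a `ledger` of carrier stoichiometries, an `electrons`
#' declaration and an optional `reversible` flag. A ledger value may also be
#' the *name* of an energy-config field (the Rnf proton stoichiometry is
#' configurable), which is substituted from `energy` at build time.
#'
#' @param config_text YAML text, a file path, or an already-parsed list.
#' @param energy an [energy_config()] supplying named parameters referenced
#'   by ledger entries.
#' @return Named list of `reaction` objects (class `reaction_set`).
#' @seealso [default_reaction_set()] for the shipped inventory.
#' @export
build_reaction_set <- function(config_text, energy = energy_config()) {
  obj <- parse_structured(config_text)
  if (is.null(obj) || length(obj) == 0L) return(structure(list(), class = "reaction_set"))
  rxns <- if (!is.null(obj$reactions)) obj$reactions else obj
  if (length(rxns) == 0L) return(structure(list(), class = "reaction_set"))
  nm <- names(rxns)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("malformed reaction config: every reaction needs a name")
  if (anyDuplicated(nm))
    stop("duplicate reaction name: ", nm[duplicated(nm)][1L])
  out <- vector("list", length(rxns))
  names(out) <- nm
  for (i in seq_along(rxns)) {
    entry <- rxns[[i]]
    if (is.null(entry$ledger))
      stop(sprintf("malformed stoichiometry in reaction '%s': missing ledger", nm[i]))
    led <- entry$ledger
    resolved <- vapply(led, function(v) {
      if (is.character(v)) {
        if (is.null(energy[[v]]))
          stop(sprintf("reaction '%s' references unknown config field '%s'", nm[i], v))
        return(as.numeric(energy[[v]]))
      }
      if (!is.numeric(v) || length(v) != 1L || is.na(v))
        stop(sprintf("malformed stoichiometry in reaction '%s'", nm[i]))
      as.numeric(v)
    }, numeric(1))
    names(resolved) <- names(led)
    out[[i]] <- reaction(nm[i], as_ledger(resolved),
                         reversible = isTRUE(entry$reversible),
                         electrons = if (is.null(entry$electrons)) 0 else entry$electrons,
                         interconversion = isTRUE(entry$interconversion))
  }
  structure(out, class = "reaction_set")
}

#' The shipped default reaction inventory
#'
#' Reactions of central carbon metabolism, the Wood-Ljungdahl pathway, the
#' Rnf/Nfn carrier-exchange enzymes, lactate cycling, the urea cycle and the
#' amino-acid degradation routes, transcribed into carrier ledgers.
#'
#' @param energy an [energy_config()]; the Rnf ledger's proton term and the
#'   methylene-THF reductase donor mode depend on it.
#' @return A `reaction_set`.
#' @export
default_reaction_set <- function(energy = energy_config()) {
  build_reaction_set(system.file("extdata", "reactions_default.yaml",
                                 package = "acetoscope", mustWork = TRUE),
                     energy = energy)
}

#' Weighted pathway over a reaction set
#'
#' @param name identifier.
#' @param steps named numeric vector of flux multipliers, names drawn from
#'   `rxns`. Irreversible reactions must carry non-negative flux.
#' @param rxns a `reaction_set`.
#' @return Object of class `pathway` with the flux-weighted net ledger.
#' @export
pathway <- function(name, steps, rxns) {
  stopifnot(is.numeric(steps))
  if (length(steps) == 0L) {
    return(structure(list(name = name, steps = numeric(0),
                          ledger = zero_ledger()), class = "pathway"))
  }
  if (is.null(names(steps)) || any(!nzchar(names(steps))))
    stop("pathway steps must be a named vector of flux multipliers")
  missing <- setdiff(names(steps), names(rxns))
  if (length(missing))
    stop("pathway '", name, "' uses unknown reaction(s): ",
         paste(missing, collapse = ", "))
  led <- zero_ledger()
  for (s in names(steps)) {
    flux <- steps[[s]]
    rxn <- rxns[[s]]
    if (flux < 0 && !rxn$reversible)
      stop("negative flux through irreversible reaction '", s, "'")
    led <- led + flux * rxn$ledger
  }
  structure(list(name = name, steps = steps, ledger = led), class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("<pathway> %s (%d steps)\n", x$name, length(x$steps)))
  print(x$ledger)
  invisible(x)
}

# Accept YAML text, a file path, or a pre-parsed list.
parse_structured <- function(x) {
  if (is.list(x)) return(x)
  if (is.null(x) || (is.character(x) && length(x) == 1L && !nzchar(x))) return(NULL)
  stopifnot(is.character(x))
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    return(yaml::read_yaml(x))
  yaml::yaml.load(paste(x, collapse = "\n"))
}
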