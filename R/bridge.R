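## Subprocess bridge to the RDKit worker.
##
## Every molecule-level primitive is one batched JSON round trip through
## `python inst/python/chembridge.py`; process startup dominates the cost of
## a call, so callers are expected to vectorize (one call for a whole block
## file, never one call per molecule).  Parsed molecule graphs are memoized
## in a package-local environment keyed by input SMILES.

.rf_state <- new.env(parent = emptyenv())

#' Locate the python interpreter used for cheminformatics primitives
#'
#' The engine delegates SMILES/SMARTS/SMIRKS handling to RDKit through a
#' batch worker script.  The interpreter is resolved from the
#' \code{rxnforge.python} option, then the \code{RXNFORGE_PYTHON} environment
#' variable, then \code{python} on the PATH.
#'
#' @return Path to the python executable.
#' @export
rf_python <- function() {
  p <- getOption("rxnforge.python", "")
  if (!nzchar(p)) p <- Sys.getenv("RXNFORGE_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) stop("no python interpreter found; set options(rxnforge.python=)")
  p
}

bridge_script <- function() {
  s <- system.file("python", "chembridge.py", package = "rxnforge")
  if (!nzchar(s)) stop("chembridge.py not found; is the package installed?")
  s
}

#' Low-level call into the RDKit worker
#'
#' @param op Operation name understood by the worker
#'   (\code{parse}, \code{match}, \code{react}, \code{inchikey}, ...).
#' @param ... Operation arguments, JSON-serializable.
#' @return Deserialized JSON response (lists, not simplified).
#' @keywords internal
bridge_call <- function(op, ...) {
  req <- c(list(op = op), list(...))
  js <- jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA, null = "null")
  out <- suppressWarnings(system2(rf_python(), shQuote(bridge_script()),
                                  input = as.character(js), stdout = TRUE,
                                  stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("cheminformatics worker failed (exit ", status, ") for op '", op, "'")
  jsonlite::fromJSON(paste(out, collapse = "\n"), simplifyVector = FALSE)
}

## ---- molecule graphs -------------------------------------------------------

new_rf_mol <- function(smiles, g) {
  atoms <- data.frame(
    symbol   = vapply(g$atoms, `[[`, "", "symbol"),
    aromatic = vapply(g$atoms, `[[`, NA, "aromatic"),
    charge   = vapply(g$atoms, function(a) as.integer(a$charge), 0L),
    n_h      = vapply(g$atoms, function(a) as.integer(a$n_h), 0L),
    degree   = vapply(g$atoms, function(a) as.integer(a$degree), 0L),
    in_ring  = vapply(g$atoms, `[[`, NA, "in_ring"),
    ring_count = vapply(g$atoms, function(a) as.integer(a$ring_count), 0L),
    outer_electrons = vapply(g$atoms, function(a) as.integer(a$outer_electrons), 0L),
    stringsAsFactors = FALSE)
  if (length(g$bonds)) {
    bonds <- data.frame(
      a1 = vapply(g$bonds, function(b) as.integer(b$a1), 0L) + 1L,
      a2 = vapply(g$bonds, function(b) as.integer(b$a2), 0L) + 1L,
      order    = vapply(g$bonds, function(b) as.integer(b$order), 0L),
      aromatic = vapply(g$bonds, `[[`, NA, "aromatic"),
      in_ring  = vapply(g$bonds, `[[`, NA, "in_ring"),
      stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                        aromatic = logical(), in_ring = logical())
  }
  n <- as.integer(g$n_atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$a1[k]; j <- bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  rings <- lapply(g$rings, function(r) as.integer(unlist(r)) + 1L)
  structure(list(smiles = smiles, canonical = g$canonical, n_atoms = n,
                 n_rings = as.integer(g$n_rings), rings = rings,
                 atoms = atoms, bonds = bonds, adj = adj),
            class = "rf_mol")
}

#' Parse SMILES into molecule graphs
#'
#' Batched: one worker round trip for the whole vector, with a session-level
#' cache so repeated fixtures are free.  Atom and bond indices on the
#' returned graphs are 1-based.
#'
#' @param smiles Character vector of SMILES.
#' @return Named list of \code{rf_mol} (or \code{NULL} for unparseable
#'   entries), in input order.
#' @export
rf_parse_smiles <- function(smiles) {
  if (is.null(.rf_state$molcache))
    .rf_state$molcache <- new.env(parent = emptyenv())
  cache <- .rf_state$molcache
  key <- function(s) paste0("s:", s)
  miss <- unique(smiles[!vapply(smiles, function(s)
    exists(key(s), envir = cache), NA)])
  if (length(miss)) {
    res <- bridge_call("parse", smiles = as.list(miss))
    for (i in seq_along(miss)) {
      g <- res[[i]]
      assign(key(miss[i]),
             if (isTRUE(g$ok)) new_rf_mol(miss[i], g) else NULL,
             envir = cache)
    }
  }
  out <- lapply(unname(smiles), function(s) get(key(s), envir = cache))
  names(out) <- if (is.null(names(smiles))) smiles else names(smiles)
  out
}

#' @export
print.rf_mol <- function(x, ...) {
  cat("<rf_mol> ", x$canonical, " (", x$n_atoms, " atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

mol_neighbors <- function(mol, i) {
  nb <- mol$adj[[i]]
  if (is.null(nb)) integer() else nb
}

#' Standard InChIKeys for a vector of SMILES
#' @param smiles Character vector.
#' @return Character vector of InChIKeys (\code{NA} where unparseable).
#' @export
rf_inchikey <- function(smiles) {
  if (!length(smiles)) return(character())
  res <- bridge_call("inchikey", smiles = as.list(smiles))
  vapply(res, function(x) if (is.null(x)) NA_character_ else x, "")
}

#' Canonical SMILES via the host toolkit
#' @param smiles Character vector.
#' @return Character vector (\code{NA} where unparseable).
#' @export
rf_canonical <- function(smiles) {
  if (!length(smiles)) return(character())
  res <- bridge_call("canon", smiles = as.list(smiles))
  vapply(res, function(x) if (is.null(x)) NA_character_ else x, "")
}
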