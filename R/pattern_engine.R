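## Keying-pattern engine: compile (extended) SMARTS, find symmetry-unique
## matches, derive onpath/offpath partitions, and evaluate named
## functional-group patterns.
##
## Two atom-level SMARTS extensions are supported on top of the standard
## primitives:
##   z<n>   -- the atom has exactly n heteroatom neighbours (directly
##             bonded atoms that are neither carbon nor hydrogen)
##   ^e<n>  -- experimental: the atom's valence-electron count equals n
##             (outer-shell electrons of the element minus formal charge)
## Extension tokens are stripped before the pattern reaches the host
## toolkit and enforced as post-filters on candidate matches.

HALOGENS <- c("F", "Cl", "Br", "I", "At")

## scan a SMARTS string; returns per-atom bracket contents and positions,
## respecting recursive-SMARTS parentheses (atoms inside $(...) are
## constraints, not pattern atoms)
scan_smarts_atoms <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  i <- 1L
  atoms <- list()   # list of (start, end, bracket: TRUE/FALSE)
  two_letter <- c("Cl", "Br")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      pdepth <- 0L
      j <- i + 1L
      while (j <= n) {
        cj <- chars[j]
        if (cj == "(") pdepth <- pdepth + 1L
        else if (cj == ")") pdepth <- pdepth - 1L
        else if (cj == "]" && pdepth == 0L) break
        j <- j + 1L
      }
      if (j > n) stop("unbalanced '[' in SMARTS: ", s)
      atoms[[length(atoms) + 1L]] <- list(start = i, end = j, bracket = TRUE)
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% two_letter) {
      atoms[[length(atoms) + 1L]] <- list(start = i, end = i + 1L,
                                          bracket = FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I", "*",
                         "b", "c", "n", "o", "p", "s")) {
      atoms[[length(atoms) + 1L]] <- list(start = i, end = i,
                                          bracket = FALSE)
      i <- i + 1L
    } else {
      i <- i + 1L       # bonds, ring closures, branches, dots, maps...
    }
  }
  atoms
}

## remove extension tokens from one bracket-atom body (top paren level
## only), returning the cleaned body and the extensions found
strip_extensions <- function(body) {
  exts <- list()
  out <- character()
  chars <- strsplit(body, "")[[1]]
  n <- length(chars)
  i <- 1L
  pdepth <- 0L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") pdepth <- pdepth + 1L
    if (ch == ")") pdepth <- pdepth - 1L
    took <- FALSE
    if (pdepth == 0L) {
      rest <- paste(chars[i:n], collapse = "")
      m <- regmatches(rest, regexpr("^z[0-9]+", rest))
      if (length(m) && m != "") {
        exts[[length(exts) + 1L]] <-
          list(kind = "HETEROATOM_NEIGHBOR_COUNT",
               value = as.integer(sub("^z", "", m)))
        i <- i + nchar(m)
        took <- TRUE
      } else {
        m <- regmatches(rest, regexpr("^\\^e[0-9]+", rest))
        if (length(m) && m != "") {
          exts[[length(exts) + 1L]] <-
            list(kind = "ELECTRON_COUNT",
                 value = as.integer(sub("^\\^e", "", m)))
          i <- i + nchar(m)
          took <- TRUE
        }
      }
    }
    if (!took) {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  body2 <- paste(out, collapse = "")
  ## tidy separators left behind by the removal: "C;;H2", ";x", "x;"
  body2 <- gsub("[;&]{2,}", ";", body2)
  body2 <- gsub("^[;&]+|[;&]+$", "", body2)
  body2 <- gsub("[;&]+(:[0-9]+)$", "\\1", body2)
  ## a bracket reduced to just a map (or to nothing) needs a wildcard
  if (body2 == "" || grepl("^:[0-9]+$", body2))
    body2 <- paste0("*", body2)
  list(body = body2, exts = exts)
}

#' Compile an (extended) SMARTS pattern
#'
#' Standard SMARTS passes through unchanged.  \code{z<n>} and \code{^e<n>}
#' atom attributes are recorded as post-filter constraints and removed from
#' the core pattern handed to the host toolkit.
#'
#' @param smarts_ext SMARTS string, possibly carrying extension tokens
#'   inside atom brackets.
#' @return An \code{rf_pattern} with \code{core_smarts}, the atom-map-number
#'   table, and the extension constraints (1-based pattern atom positions).
#' @export
compile_pattern <- function(smarts_ext) {
  atoms <- scan_smarts_atoms(smarts_ext)
  chars <- strsplit(smarts_ext, "")[[1]]
  pieces <- character()
  pos <- 1L
  constraints <- list()
  for (k in seq_along(atoms)) {
    a <- atoms[[k]]
    if (a$start > pos)
      pieces <- c(pieces, paste(chars[pos:(a$start - 1L)], collapse = ""))
    seg <- paste(chars[a$start:a$end], collapse = "")
    if (a$bracket) {
      body <- substr(seg, 2L, nchar(seg) - 1L)
      st <- strip_extensions(body)
      for (e in st$exts)
        constraints[[length(constraints) + 1L]] <-
          c(list(atom_pos = k), e)
      seg <- paste0("[", st$body, "]")
    }
    pieces <- c(pieces, seg)
    pos <- a$end + 1L
  }
  if (pos <= length(chars))
    pieces <- c(pieces, paste(chars[pos:length(chars)], collapse = ""))
  core <- paste(pieces, collapse = "")
  info <- bridge_call("smarts_info", smarts = list(core))[[1]]
  if (!isTRUE(info$ok))
    stop("SMARTS compile error in '", smarts_ext, "': ", info$error)
  map_nums <- as.integer(unlist(info$map_nums))
  structure(list(source = smarts_ext, core_smarts = core,
                 n_atoms = as.integer(info$n_atoms),
                 map_nums = map_nums,           # per pattern atom, 0 = none
                 constraints = constraints),
            class = "rf_pattern")
}

#' @export
print.rf_pattern <- function(x, ...) {
  cat("<rf_pattern> ", x$source, "\n  core: ", x$core_smarts,
      " (", x$n_atoms, " atoms, ", length(x$constraints),
      " extension constraint(s))\n", sep = "")
  invisible(x)
}

heteroatom_neighbor_count <- function(mol, i) {
  nb <- mol_neighbors(mol, i)
  sum(!(mol$atoms$symbol[nb] %in% c("C", "H")))
}

check_constraints <- function(p, mol, match_atoms) {
  for (cs in p$constraints) {
    i <- match_atoms[cs$atom_pos]
    val <- switch(cs$kind,
      HETEROATOM_NEIGHBOR_COUNT = heteroatom_neighbor_count(mol, i),
      ELECTRON_COUNT = mol$atoms$outer_electrons[i] - mol$atoms$charge[i],
      stop("unknown constraint kind: ", cs$kind))
    if (val != cs$value) return(FALSE)
  }
  TRUE
}

make_binding <- function(p, mol, match_atoms) {
  am <- match_atoms[p$map_nums > 0L]
  names(am) <- as.character(p$map_nums[p$map_nums > 0L])
  onpath <- sort(unique(match_atoms))
  all_atoms <- seq_len(mol$n_atoms)
  bond_on <- which(mol$bonds$a1 %in% onpath & mol$bonds$a2 %in% onpath)
  structure(list(mol = mol,
                 matched_atoms = match_atoms,   # pattern-atom order
                 atom_map = am,                 # map number -> atom index
                 onpath_atoms = onpath,
                 offpath_atoms = setdiff(all_atoms, onpath),
                 onpath_bonds = bond_on,
                 offpath_bonds = setdiff(seq_len(nrow(mol$bonds)), bond_on)),
            class = "rf_binding")
}

#' @export
print.rf_binding <- function(x, ...) {
  cat("<rf_binding> onpath atoms {",
      paste(x$onpath_atoms, collapse = ", "), "} of ",
      x$mol$canonical, "\n", sep = "")
  invisible(x)
}

#' Batched matching: one worker round trip for a whole molecule panel
#'
#' @param p An \code{rf_pattern}.
#' @param mols List of \code{rf_mol}.
#' @return List (one per molecule) of lists of \code{rf_binding}.
#' @export
find_matches_many <- function(p, mols) {
  stopifnot(inherits(p, "rf_pattern"))
  smiles <- vapply(mols, function(m) m$smiles, "")
  res <- bridge_call("match", smarts = p$core_smarts,
                     smiles = as.list(smiles), uniquify = FALSE)
  if (!isTRUE(res$ok)) stop(res$error)
  lapply(seq_along(mols), function(k) {
    mol <- mols[[k]]
    raw <- res$matches[[k]]
    if (is.null(raw)) stop("unsanitizable molecule: ", smiles[k])
    out <- list()
    seen <- character()
    for (m in raw) {
      idx <- as.integer(unlist(m)) + 1L
      if (!check_constraints(p, mol, idx)) next
      key <- paste(sort(idx), collapse = ",")
      if (key %in% seen) next          # automorphic image of a kept match
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- make_binding(p, mol, idx)
    }
    out
  })
}

#' Find matches of a compiled pattern in a molecule
#'
#' Matches are symmetry-deduplicated: automorphic matches covering the same
#' atom set count once (first image in toolkit order is kept); distinct atom
#' sets count separately.  Extension constraints are applied as
#' post-filters.  Each returned binding carries the atom-map table and the
#' onpath/offpath partition of the molecule's atoms and bonds.
#'
#' @param p An \code{rf_pattern} from \code{\link{compile_pattern}}.
#' @param mol An \code{rf_mol} from \code{\link{rf_parse_smiles}}.
#' @return List of \code{rf_binding}.
#' @export
find_matches <- function(p, mol) {
  stopifnot(inherits(mol, "rf_mol"))
  find_matches_many(p, list(mol))[[1]]
}

## ---- group library --------------------------------------------------------

#' Read a functional-group library
#'
#' A group library is a TSV with columns \code{name}, \code{smarts},
#' \code{origin} (0-based position of the group's designated origin atom
#' within its SMARTS).  Logic programs refer to groups by name
#' ("is the origin of amine1 group").
#'
#' @param path TSV path.
#' @return Named list of group definitions.
#' @export
read_group_library <- function(path) {
  ## no comment.char: '#' is an atomic-number primitive in SMARTS
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "smarts", "origin") %in% names(df)))
  lib <- list()
  for (k in seq_len(nrow(df))) {
    patt <- compile_pattern(df$smarts[k])   # errors if it does not compile
    if (df$origin[k] < 0L || df$origin[k] >= patt$n_atoms)
      stop("group '", df$name[k], "': origin position ", df$origin[k],
           " outside its pattern (", patt$n_atoms, " atoms)")
    lib[[df$name[k]]] <- list(name = df$name[k], smarts = df$smarts[k],
                              origin = as.integer(df$origin[k]),
                              pattern = patt)
  }
  lib
}

#' The group library shipped with the package
#'
#' Seeded with the groups named or implied by the stock transforms:
#' primary/secondary/tertiary amines, carboxylic acid, boronic acid,
#' sulfonamide, azide, terminal alkyne, and one aryl halide per halogen.
#' Cached per session.
#'
#' @return Named list of group definitions.
#' @export
default_group_library <- function() {
  if (is.null(.rf_state$groups)) {
    path <- system.file("extdata", "group_library.tsv", package = "rxnforge")
    .rf_state$groups <- read_group_library(path)
  }
  .rf_state$groups
}

## batched: origin-atom hits of one named group across many molecules
group_hits_many <- function(lib, name, mols) {
  g <- lib[[name]]
  if (is.null(g))
    stop("unknown group '", name, "'; known groups: ",
         paste(names(lib), collapse = ", "))
  bindings <- find_matches_many(g$pattern, mols)
  lapply(bindings, function(bl)
    sort(unique(vapply(bl, function(b) b$matched_atoms[g$origin + 1L], 0L))))
}

#' Origin-atom hits of a named group in a molecule
#'
#' @param lib A group library.
#' @param name Group name.
#' @param mol An \code{rf_mol}.
#' @return Sorted integer vector of molecule atom indices matched by the
#'   group's origin atom, across all symmetry-unique matches.
#' @export
group_hits <- function(lib, name, mol) {
  group_hits_many(lib, name, list(mol))[[1]]
}
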