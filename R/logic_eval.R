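## Evaluate a logic program against one pattern match (binding).
##
## Semantics in brief:
##  * a fresh rating starts at 50; "slightly/moderately/strongly/severely"
##    map to steps 5/10/20/35; the final value is clamped to [0, 100];
##  * "kill" is monotone and short-circuits the rest of the program;
##  * a subject that denotes several objects ("alpha to atom 2") is tested
##    existentially: the condition holds if any object in the (where-
##    filtered) set satisfies the predicate combination;
##  * "and if"/"or if" chain strictly left to right with short-circuiting.

MAGNITUDE_STEPS <- c(SLIGHTLY = 5L, MODERATELY = 10L, STRONGLY = 20L,
                     SEVERELY = 35L)

new_rating <- function(base = 50L)
  list(base = as.integer(base), deltas = list(), killed = FALSE)

#' Final value of a rating
#'
#' base + the signed magnitude steps, clamped to [0, 100].
#'
#' @param r A rating as carried on an \code{rf_outcome}.
#' @return Integer in [0, 100].
#' @export
rating_value <- function(r) {
  s <- r$base
  for (d in r$deltas)
    s <- s + if (d$direction == "RAISE") d$step else -d$step
  max(0L, min(100L, as.integer(s)))
}

new_outcome <- function() {
  structure(list(rating = new_rating(), ghosts = character(),
                 trace = list()), class = "rf_outcome")
}

#' @export
print.rf_outcome <- function(x, ...) {
  cat("<rf_outcome> rating ", rating_value(x$rating),
      if (x$rating$killed) " (killed)" else "",
      ", ", length(x$ghosts), " ghost(s), ",
      length(x$trace), " statement evaluation(s)\n", sep = "")
  invisible(x)
}

new_eval_env <- function(group_hits = list()) {
  env <- new.env(parent = emptyenv())
  env$vars <- list()
  env$sets <- list()
  env$group_hits <- group_hits
  env
}

obj_atom <- function(i) list(otype = "atom", idx = as.integer(i))
obj_bond <- function(i) list(otype = "bond", idx = as.integer(i))
obj_ring <- function(i, atoms) list(otype = "ring", idx = as.integer(i),
                                    atoms = atoms)
obj_molecule <- function() list(otype = "molecule")

eval_error <- function(...) stop("logic evaluation error: ", ...)

map_atom <- function(b, n) {
  i <- b$atom_map[as.character(n)]
  if (is.na(i))
    eval_error("atom map ", n, " is not bound by the keying pattern")
  unname(i)
}

find_bond_row <- function(mol, i, j) {
  hit <- which((mol$bonds$a1 == i & mol$bonds$a2 == j) |
               (mol$bonds$a1 == j & mol$bonds$a2 == i))
  if (length(hit)) hit[1] else NA_integer_
}

#' Resolve a subject to its chemical objects
#'
#' \code{atom N} yields the bound atom; \code{alpha to atom N} all atoms
#' directly bonded to it (onpath and offpath alike -- a where-clause
#' restricts further); \code{bond between atom I and atom J} the molecule
#' bond between the two bound atoms; \code{molecule} the whole-molecule
#' object; a variable its current loop/set value.
#'
#' @param s Subject AST node.
#' @param b An \code{rf_binding}.
#' @param env Evaluation environment.
#' @return List of chemical objects.
#' @export
eval_subject <- function(s, b, env) {
  switch(s$stype,
    ATOM = list(obj_atom(map_atom(b, s$atom_refs[1]))),
    ALPHA_TO_ATOM = lapply(mol_neighbors(b$mol, map_atom(b, s$atom_refs[1])),
                           obj_atom),
    BOND = {
      i <- map_atom(b, s$atom_refs[1])
      j <- map_atom(b, s$atom_refs[2])
      row <- find_bond_row(b$mol, i, j)
      if (is.na(row))
        eval_error("no bond between mapped atoms ", s$atom_refs[1], " and ",
                   s$atom_refs[2], " (transform/pattern inconsistency)")
      list(obj_bond(row))
    },
    MOLECULE = list(obj_molecule()),
    VARIABLE = {
      v <- env$vars[[s$var_name]]
      if (is.null(v)) v <- env$sets[[s$var_name]]
      if (is.null(v))
        eval_error("unbound variable '", s$var_name, "'")
      if (identical(v$otype, NULL)) v else list(v)   # set vs single object
    },
    eval_error("unknown subject type ", s$stype))
}

obj_is_onpath <- function(o, b) {
  switch(o$otype,
    atom = o$idx %in% b$onpath_atoms,
    bond = o$idx %in% b$onpath_bonds,
    ring = any(o$atoms %in% b$onpath_atoms),
    molecule = TRUE)
}

where_filter <- function(objs, where, b) {
  if (where == "NONE") return(objs)
  keep <- vapply(objs, function(o)
    o$otype == "molecule" ||
      (obj_is_onpath(o, b) == (where == "ONPATH")), NA)
  objs[keep]
}

## entity class membership for a single object
entity_matches_object <- function(ent, o, mol) {
  if (ent$eclass %in% c("atom", "heteroatom", "halogen", "charge")) {
    if (o$otype != "atom") return(FALSE)
    sym <- mol$atoms$symbol[o$idx]
    return(switch(ent$eclass,
      atom = is.null(ent$element) || sym == ent$element,
      heteroatom = !(sym %in% c("C", "H")),
      halogen = sym %in% HALOGENS,
      charge = if (ent$sign > 0) mol$atoms$charge[o$idx] > 0
               else mol$atoms$charge[o$idx] < 0))
  }
  if (ent$eclass == "bond") return(o$otype == "bond")
  if (ent$eclass == "ring") return(o$otype == "ring")
  FALSE
}

qual_atom_test <- function(name, i, mol) {
  a <- mol$atoms
  switch(name,
    aromatic = a$aromatic[i],
    aliphatic = !a$aromatic[i],
    cyclic = a$in_ring[i],
    charged = a$charge[i] != 0L,
    neutral = a$charge[i] == 0L,
    "primary center" = carbon_center_degree(mol, i) == 1L,
    "secondary center" = carbon_center_degree(mol, i) == 2L,
    "tertiary center" = carbon_center_degree(mol, i) == 3L,
    "quaternary center" = carbon_center_degree(mol, i) == 4L,
    eval_error("qualitative predicate '", name,
               "' is not applicable to an atom"))
}

carbon_center_degree <- function(mol, i) {
  if (mol$atoms$symbol[i] != "C") return(-1L)
  sum(mol$atoms$symbol[mol_neighbors(mol, i)] == "C")
}

qual_bond_test <- function(name, row, mol) {
  bd <- mol$bonds
  switch(name,
    aromatic = bd$aromatic[row],
    cyclic = bd$in_ring[row],
    "single bond" = !bd$aromatic[row] & bd$order[row] == 1L,
    "double bond" = bd$order[row] == 2L,
    "triple bond" = bd$order[row] == 3L,
    eval_error("qualitative predicate '", name,
               "' is not applicable to a bond"))
}

qual_ring_test <- function(name, o, mol) {
  switch(name,
    aromatic = all(mol$atoms$aromatic[o$atoms]),
    eval_error("qualitative predicate '", name,
               "' is not applicable to a ring"))
}

eval_qualitative <- function(pr, o, mol, env) {
  if (pr$name == "entity")
    return(entity_matches_object(pr$entity, o, mol))
  switch(o$otype,
    atom = qual_atom_test(pr$name, o$idx, mol),
    bond = qual_bond_test(pr$name, o$idx, mol),
    ring = qual_ring_test(pr$name, o, mol),
    molecule = eval_error("qualitative predicate '", pr$name,
                          "' is not applicable to the whole molecule"))
}

eval_group_origin <- function(pr, o, mol, env) {
  if (o$otype != "atom")
    eval_error("'origin of ", pr$name, " group' applies to atoms only")
  hits <- env$group_hits[[pr$name]]
  if (is.null(hits))
    eval_error("group '", pr$name, "' was not resolved for this molecule")
  o$idx %in% hits
}

## counting for quantitative predicates: attached features for an atom,
## whole-molecule totals for the molecule subject
count_entity <- function(ent, o, mol, env) {
  if (o$otype == "atom") {
    i <- o$idx
    nb <- mol_neighbors(mol, i)
    sym <- mol$atoms$symbol[nb]
    return(switch(ent$eclass,
      hydrogen = mol$atoms$n_h[i],
      atom = if (is.null(ent$element)) length(nb)
             else sum(sym == ent$element),
      heteroatom = sum(!(sym %in% c("C", "H"))),
      halogen = sum(sym %in% HALOGENS),
      charge = if (ent$sign > 0) as.integer(mol$atoms$charge[i] > 0)
               else as.integer(mol$atoms$charge[i] < 0),
      ring = mol$atoms$ring_count[i],
      group = sum(nb %in% env$group_hits[[ent$group]]) +
              as.integer(i %in% env$group_hits[[ent$group]]),
      eval_error("cannot count '", ent$eclass, "' on an atom")))
  }
  if (o$otype == "molecule") {
    sym <- mol$atoms$symbol
    return(switch(ent$eclass,
      hydrogen = sum(mol$atoms$n_h),
      atom = if (is.null(ent$element)) mol$n_atoms
             else sum(sym == ent$element),
      heteroatom = sum(!(sym %in% c("C", "H"))),
      halogen = sum(sym %in% HALOGENS),
      charge = if (ent$sign > 0) sum(mol$atoms$charge > 0)
               else sum(mol$atoms$charge < 0),
      ring = mol$n_rings,
      group = length(env$group_hits[[ent$group]]),
      eval_error("cannot count '", ent$eclass, "' on the molecule")))
  }
  eval_error("quantitative predicates apply to atoms or the molecule, not ",
             o$otype)
}

eval_quantitative <- function(pr, o, mol, env) {
  n <- count_entity(pr$counted, o, mol, env)
  switch(pr$quantifier,
    AT_LEAST = n >= pr$count,
    AT_MOST = n <= pr$count,
    EXACTLY = n == pr$count)
}

eval_predicate <- function(pr, o, mol, env) {
  v <- switch(pr$ptype,
    QUALITATIVE = eval_qualitative(pr, o, mol, env),
    GROUP_ORIGIN = eval_group_origin(pr, o, mol, env),
    QUANTITATIVE = eval_quantitative(pr, o, mol, env))
  if (isTRUE(pr$negated)) !v else v
}

object_passes <- function(c, o, mol, env) {
  vals <- vapply(c$predicates, eval_predicate, NA, o = o, mol = mol,
                 env = env)
  if (length(vals) == 1L) return(vals)
  if (identical(c$pred_comb, "OR")) any(vals) else all(vals)
}

#' Evaluate one condition under a binding
#'
#' Subjects are joined by the condition's subject combinator; a where
#' clause filters each subject's object set before testing; relation
#' \code{is} tests qualitative/group predicates, \code{has} counts.
#'
#' @param c Condition AST node.
#' @param b An \code{rf_binding}.
#' @param env Evaluation environment (see \code{\link{run_program}}).
#' @return Logical scalar.
#' @export
eval_condition <- function(c, b, env) {
  subj_vals <- vapply(c$subjects, function(s) {
    objs <- where_filter(eval_subject(s, b, env), c$where, b)
    if (!length(objs)) return(FALSE)
    any(vapply(objs, function(o) object_passes(c, o, b$mol, env), NA))
  }, NA)
  if (length(subj_vals) == 1L) return(subj_vals)
  if (identical(c$subj_comb, "OR")) any(subj_vals) else all(subj_vals)
}

apply_action <- function(a, out) {
  if (a$atype == "KILL") {
    out$rating$killed <- TRUE
  } else if (a$atype == "ADJUST_RATING") {
    out$rating$deltas[[length(out$rating$deltas) + 1L]] <-
      list(direction = a$direction, magnitude = a$magnitude,
           step = MAGNITUDE_STEPS[[a$magnitude]])
  } else if (a$atype == "GHOST") {
    out$ghosts <- c(out$ghosts, a$ghost_fragment)
  }
  out
}

#' Run one statement
#'
#' Clauses evaluate left to right; \code{and if} conjoins, \code{or if}
#' disjoins, both short-circuit.  If the composite is true the action fires
#' exactly once.  Every evaluation is appended to the outcome's trace.
#'
#' @param st Statement AST node.
#' @param b An \code{rf_binding}.
#' @param env Evaluation environment.
#' @param out An \code{rf_outcome} to update.
#' @return The updated outcome.
#' @export
run_statement <- function(st, b, env, out) {
  acc <- NA
  for (cl in st$clauses) {
    if (cl$comb == "FIRST") {
      acc <- eval_condition(cl$condition, b, env)
    } else if (cl$comb == "AND_IF") {
      if (isTRUE(acc)) acc <- eval_condition(cl$condition, b, env)
    } else {                                   # OR_IF
      if (!isTRUE(acc)) acc <- eval_condition(cl$condition, b, env)
    }
  }
  if (isTRUE(acc)) out <- apply_action(st$action, out)
  out$trace[[length(out$trace) + 1L]] <-
    list(statement = ser_statement(st), fired = isTRUE(acc))
  out
}

## enumerate objects of an entity class for loops and set definitions,
## in canonical (ascending index) order
entity_objects <- function(ent, b, env, where = "NONE",
                           container = list(ctype = "MOLECULE")) {
  mol <- b$mol
  objs <- switch(container$ctype,
    MOLECULE = ,
    RINGS = {
      if (container$ctype == "RINGS" || ent$eclass == "ring") {
        cand <- lapply(seq_along(mol$rings), function(k)
          obj_ring(k, mol$rings[[k]]))
        if (container$ctype == "RINGS" && ent$eclass != "ring")
          cand <- lapply(sort(unique(unlist(mol$rings))), obj_atom)
        cand
      } else if (ent$eclass == "bond") {
        lapply(seq_len(nrow(mol$bonds)), obj_bond)
      } else if (ent$eclass == "hydrogen") {
        eval_error("implicit hydrogens cannot be iterated")
      } else if (ent$eclass == "group") {
        hits <- env$group_hits[[ent$group]]
        if (is.null(hits))
          eval_error("group '", ent$group,
                     "' was not resolved for this molecule")
        lapply(hits, obj_atom)
      } else {
        lapply(seq_len(mol$n_atoms), obj_atom)
      }
    },
    NAMED_SET = {
      s <- env$sets[[container$name]]
      if (is.null(s))
        eval_error("undefined set '", container$name, "'")
      s
    })
  keep <- vapply(objs, entity_matches_object, NA, ent = ent, mol = mol)
  ## groups and plain rings/bonds matched structurally above
  if (ent$eclass %in% c("group"))
    keep <- rep(TRUE, length(objs))
  objs <- objs[keep]
  where_filter(objs, where, b)
}

#' Run a loop
#'
#' Objects matching the iterand and where filter are enumerated in
#' canonical atom/bond/ring index order; the loop variable is bound for
#' each iteration and removed afterwards.
#'
#' @inheritParams run_statement
#' @param l Loop AST node.
#' @return The updated outcome.
#' @export
run_loop <- function(l, b, env, out) {
  objs <- entity_objects(l$iterand, b, env, l$where, l$container)
  prev <- env$vars[[l$var_name]]
  for (o in objs) {
    env$vars[[l$var_name]] <- o
    out <- run_items(l$body$items, b, env, out)
    if (out$rating$killed) break
  }
  if (is.null(prev)) env$vars[[l$var_name]] <- NULL
  else env$vars[[l$var_name]] <- prev
  out
}

run_items <- function(items, b, env, out) {
  for (it in items) {
    if (out$rating$killed) break               # kill short-circuits
    if (it$kind == "statement") out <- run_statement(it, b, env, out)
    else if (it$kind == "loop") out <- run_loop(it, b, env, out)
    else if (it$kind == "setdef")
      env$sets[[it$name]] <- entity_objects(it$entity, b, env, it$where)
  }
  out
}

resolve_group_hits <- function(p, mol, groups) {
  refs <- program_group_refs(p)
  hits <- lapply(refs, function(g) group_hits(groups, g, mol))
  names(hits) <- refs
  hits
}

#' Evaluate a logic program against one binding
#'
#' Statements and loops run in file order against a fresh rating
#' (base 50); \code{kill} short-circuits the remainder.
#'
#' @param p An \code{rf_program}.
#' @param b An \code{rf_binding}.
#' @param groups Group library used to resolve group-origin predicates.
#' @param group_hits Precomputed per-group origin hits for this molecule
#'   (named list of integer vectors); computed on demand when omitted.
#' @return An \code{rf_outcome}: rating (with kill flag), designated ghost
#'   fragments, and a per-statement trace.
#' @export
run_program <- function(p, b, groups = default_group_library(),
                        group_hits = NULL) {
  stopifnot(inherits(b, "rf_binding"))
  if (is.null(group_hits))
    group_hits <- resolve_group_hits(p, b$mol, groups)
  env <- new_eval_env(group_hits)
  run_items(p$items, b, env, new_outcome())
}
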