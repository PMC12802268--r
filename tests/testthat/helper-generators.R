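# Random program generators for property-style tests.
#
# gen_program() draws syntactically valid ASTs from the full grammar (for
# round-trip fuzzing); gen_eval_program() draws a restricted,
# evaluation-safe subset: subjects resolve under a given binding and every
# predicate is applicable to its subject's object class.

gen_entity_atomish <- function() {
  k <- sample(5L, 1)
  switch(k,
         list(kind = "entity", eclass = "atom", element = NULL,
              sign = NULL, group = NULL),
         list(kind = "entity", eclass = "atom",
              element = sample(c("C", "N", "O", "S", "Cl", "Br", "I"), 1),
              sign = NULL, group = NULL),
         list(kind = "entity", eclass = "heteroatom", element = NULL,
              sign = NULL, group = NULL),
         list(kind = "entity", eclass = "halogen", element = NULL,
              sign = NULL, group = NULL),
         list(kind = "entity", eclass = "charge", element = NULL,
              sign = sample(c(1L, -1L), 1), group = NULL))
}

gen_entity_countable <- function() {
  if (stats::runif(1) < 0.3)
    return(list(kind = "entity", eclass = sample(c("hydrogen", "ring"), 1),
                element = NULL, sign = NULL, group = NULL))
  gen_entity_atomish()
}

gen_predicate <- function(relation) {
  if (relation == "IS") {
    k <- sample(3L, 1)
    if (k == 1L)
      return(list(kind = "predicate", ptype = "QUALITATIVE",
                  name = sample(c("aromatic", "aliphatic", "cyclic",
                                  "charged", "neutral", "primary center",
                                  "secondary center"), 1),
                  entity = NULL, negated = stats::runif(1) < 0.2))
    if (k == 2L)
      return(list(kind = "predicate", ptype = "QUALITATIVE",
                  name = "entity", entity = gen_entity_atomish(),
                  negated = stats::runif(1) < 0.2))
    list(kind = "predicate", ptype = "GROUP_ORIGIN",
         name = sample(c("amine1", "amine2", "carboxylic_acid"), 1),
         negated = stats::runif(1) < 0.2)
  } else {
    list(kind = "predicate", ptype = "QUANTITATIVE",
         quantifier = sample(c("AT_LEAST", "AT_MOST", "EXACTLY"), 1),
         count = sample(0:3, 1), counted = gen_entity_countable(),
         negated = stats::runif(1) < 0.2)
  }
}

gen_subject <- function(maps, vars) {
  pool <- c("ATOM", "ALPHA", "MOL")
  if (length(vars)) pool <- c(pool, "VAR")
  switch(sample(pool, 1),
    ATOM = list(kind = "subject", stype = "ATOM",
                atom_refs = sample(maps, 1)),
    ALPHA = list(kind = "subject", stype = "ALPHA_TO_ATOM",
                 atom_refs = sample(maps, 1)),
    MOL = list(kind = "subject", stype = "MOLECULE", atom_refs = integer()),
    VAR = list(kind = "subject", stype = "VARIABLE", atom_refs = integer(),
               var_name = sample(vars, 1)))
}

gen_condition <- function(maps, vars, eval_safe = FALSE) {
  ns <- sample(1:2, 1, prob = c(0.8, 0.2))
  subjects <- lapply(seq_len(ns), function(i) gen_subject(maps, vars))
  if (eval_safe && any(vapply(subjects, `[[`, "", "stype") == "MOLECULE"))
    subjects <- list(list(kind = "subject", stype = "MOLECULE",
                          atom_refs = integer()))
  mol_subj <- any(vapply(subjects, `[[`, "", "stype") == "MOLECULE")
  relation <- if (eval_safe && mol_subj) "HAS"
              else sample(c("IS", "HAS"), 1)
  np <- sample(1:2, 1, prob = c(0.8, 0.2))
  predicates <- lapply(seq_len(np), function(i) gen_predicate(relation))
  if (eval_safe)           # group hits are not resolved in fuzz runs
    predicates <- lapply(predicates, function(pr) {
      if (pr$ptype == "GROUP_ORIGIN") gen_predicate("HAS") else pr
    })
  relation2 <- relation
  if (eval_safe && any(vapply(predicates, `[[`, "", "ptype") ==
                       "QUANTITATIVE")) relation2 <- "HAS"
  list(kind = "condition", subjects = subjects,
       subj_comb = if (ns > 1L) sample(c("AND", "OR"), 1) else NA_character_,
       relation = relation2, predicates = predicates,
       pred_comb = if (np > 1L) sample(c("AND", "OR"), 1) else NA_character_,
       where = sample(c("NONE", "NONE", "OFFPATH", "ONPATH"), 1))
}

gen_action <- function(kill_ok = TRUE) {
  pool <- c("ADJ", "ADJ", "GHOST", if (kill_ok) "KILL")
  switch(sample(pool, 1),
    KILL = list(kind = "action", atype = "KILL"),
    ADJ = list(kind = "action", atype = "ADJUST_RATING",
               direction = sample(c("RAISE", "LOWER"), 1),
               magnitude = sample(c("SLIGHTLY", "MODERATELY", "STRONGLY",
                                    "SEVERELY"), 1)),
    GHOST = list(kind = "action", atype = "GHOST", ghost_fragment = "O"))
}

gen_statement <- function(maps, vars, eval_safe = FALSE, kill_ok = TRUE) {
  nc <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
  clauses <- lapply(seq_len(nc), function(i)
    list(comb = if (i == 1L) "FIRST" else sample(c("AND_IF", "OR_IF"), 1),
         condition = gen_condition(maps, vars, eval_safe)))
  list(kind = "statement", clauses = clauses,
       action = gen_action(kill_ok))
}

gen_loop <- function(maps, vars, depth, eval_safe, kill_ok) {
  v <- paste0("v", length(vars) + 1L, "_", sample(999L, 1))
  iterand <- if (eval_safe) gen_entity_atomish() else {
    e <- gen_entity_atomish()
    if (stats::runif(1) < 0.2)
      e <- list(kind = "entity", eclass = "ring", element = NULL,
                sign = NULL, group = NULL)
    e
  }
  container <- if (!eval_safe && iterand$eclass == "ring")
    list(ctype = "RINGS") else list(ctype = "MOLECULE")
  body <- gen_items(maps, c(vars, v), depth - 1L, eval_safe, kill_ok)
  list(kind = "loop", iterand = iterand,
       where = sample(c("NONE", "OFFPATH", "ONPATH"), 1), var_name = v,
       container = container,
       body = structure(list(kind = "program", items = body),
                        class = "rf_program"))
}

gen_items <- function(maps, vars, depth, eval_safe, kill_ok) {
  n <- sample(1:3, 1)
  lapply(seq_len(n), function(i) {
    if (depth > 0L && stats::runif(1) < 0.3)
      gen_loop(maps, vars, depth, eval_safe, kill_ok)
    else gen_statement(maps, vars, eval_safe, kill_ok)
  })
}

gen_program <- function(maps = 1:2, depth = 2L, eval_safe = FALSE,
                        kill_ok = TRUE) {
  structure(list(kind = "program",
                 items = gen_items(maps, character(), depth, eval_safe,
                                   kill_ok)),
            class = "rf_program")
}

# evaluation-safe variant: subjects restricted to the binding's map
# numbers, loops over atoms only, no group predicates
gen_eval_program <- function(maps, depth = 1L, kill_ok = TRUE)
  gen_program(maps = maps, depth = depth, eval_safe = TRUE,
              kill_ok = kill_ok)
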