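# Logic evaluation: subjects, conditions, statements, loops, ratings.

iodo_binding <- function() {
  mols <- panel_mols()
  find_matches(compile_pattern("[c:1][I:2]"), mols[["iodobenzene"]])[[1]]
}

env0 <- function() rxnforge:::new_eval_env()

first_cond <- function(src) parse_program(src)$items[[1]]$clauses[[1]]$condition

test_that("subjects resolve to the documented object sets", {
  b <- iodo_binding()
  s_atom <- parse_program("if atom 1 is aromatic then kill"
  )$items[[1]]$clauses[[1]]$condition$subjects[[1]]
  objs <- eval_subject(s_atom, b, env0())
  expect_length(objs, 1L)
  expect_equal(objs[[1]]$idx, unname(b$atom_map["1"]))

  # alpha to the ipso carbon: the iodine plus the two ortho carbons
  s_alpha <- first_cond("if alpha to atom 1 is aromatic then kill")$subjects[[1]]
  alpha <- eval_subject(s_alpha, b, env0())
  expect_length(alpha, 3L)
  syms <- b$mol$atoms$symbol[vapply(alpha, `[[`, 0L, "idx")]
  expect_setequal(syms, c("I", "C", "C"))

  # offpath restriction drops the onpath iodine
  off <- rxnforge:::where_filter(alpha, "OFFPATH", b)
  expect_length(off, 2L)
  expect_true(all(b$mol$atoms$symbol[vapply(off, `[[`, 0L, "idx")] == "C"))

  s_bond <- first_cond("if bond between atom 1 and atom 2 is aromatic then kill"
  )$subjects[[1]]
  bd <- eval_subject(s_bond, b, env0())
  expect_length(bd, 1L)
  expect_equal(bd[[1]]$otype, "bond")

  # no molecule bond between unbonded mapped atoms -> evaluation error
  mols <- panel_mols()
  b14 <- find_matches(compile_pattern("[I:1][c:2][c][c:3]"),
                      mols[["iodobenzene"]])[[1]]
  s_bad <- first_cond("if bond between atom 1 and atom 3 is aromatic then kill"
  )$subjects[[1]]
  expect_error(eval_subject(s_bad, b14, env0()), "no bond between")

  s_var <- list(kind = "subject", stype = "VARIABLE",
                atom_refs = integer(), var_name = "ghost_var")
  expect_error(eval_subject(s_var, b, env0()), "unbound variable")
})

test_that("conditions evaluate qualitative and quantitative predicates", {
  mols <- panel_mols()
  benz_b <- find_matches(compile_pattern("[#6:1]"), mols[["benzene"]])[[1]]
  chx_b <- find_matches(compile_pattern("[#6:1]"), mols[["cyclohexane"]])[[1]]
  cond_arom <- first_cond("if atom 1 is aromatic then kill")
  expect_true(eval_condition(cond_arom, benz_b, env0()))
  expect_false(eval_condition(cond_arom, chx_b, env0()))

  # chloroform's carbon has 3 Cl: "at most 2 chlorines" fails there,
  # holds for dichloromethane
  ccl <- first_cond("if atom 1 has at most 2 chlorines then kill")
  chcl3 <- find_matches(compile_pattern("[CX4:1]"), mols[["chloroform"]])[[1]]
  ch2cl2 <- find_matches(compile_pattern("[CX4:1]"),
                         mols[["dichloromethane"]])[[1]]
  expect_false(eval_condition(ccl, chcl3, env0()))
  expect_true(eval_condition(ccl, ch2cl2, env0()))

  # diethylamine's nitrogen carries exactly one hydrogen
  nh <- first_cond("if atom 1 has one hydrogen then kill")
  n_b <- find_matches(compile_pattern("[NX3:1]"), mols[["diethylamine"]])[[1]]
  expect_true(eval_condition(nh, n_b, env0()))
  expect_false(eval_condition(
    first_cond("if atom 1 has two hydrogens then kill"), n_b, env0()))

  # "at least 1 carbon atom attached to it"
  expect_true(eval_condition(
    first_cond("if atom 1 has at least 1 carbon atom attached to it then kill"),
    n_b, env0()))

  # subject OR: either atom satisfying the predicate suffices
  b_ci <- iodo_binding()
  expect_true(eval_condition(
    first_cond("if atom 1 or atom 2 is carbon atom then kill"),
    b_ci, env0()))
  expect_false(eval_condition(
    first_cond("if atom 1 and atom 2 is carbon atom then kill"),
    b_ci, env0()))

  # typing error: aromaticity of a whole molecule is meaningless
  expect_error(eval_condition(
    first_cond("if molecule is aromatic then kill"), b_ci, env0()),
    "not applicable")
})

test_that("and-if / or-if agree with boolean conjunction and disjunction", {
  b <- iodo_binding()
  # realized truth values on iodobenzene's binding:
  tc <- "atom 1 is carbon atom"     # TRUE
  fc <- "atom 1 is nitrogen atom"   # FALSE
  t2 <- "atom 2 is iodine atom"     # TRUE
  f2 <- "atom 2 is oxygen atom"     # FALSE
  fired <- function(c1, c2, op) {
    st <- parse_program(paste("if", c1, op, c2, "then kill"))$items[[1]]
    out <- run_statement(st, b, env0(), rxnforge:::new_outcome())
    out$rating$killed
  }
  # AND_IF truth table
  expect_true(fired(tc, t2, "and if"))
  expect_false(fired(tc, f2, "and if"))
  expect_false(fired(fc, t2, "and if"))
  expect_false(fired(fc, f2, "and if"))
  # OR_IF truth table
  expect_true(fired(tc, t2, "or if"))
  expect_true(fired(tc, f2, "or if"))
  expect_true(fired(fc, t2, "or if"))
  expect_false(fired(fc, f2, "or if"))
})

test_that("statements fire actions once and keep a trace", {
  mols <- panel_mols()
  benz_b <- find_matches(compile_pattern("[#6:1]"), mols[["benzene"]])[[1]]
  st <- parse_program(
    "if atom 1 is carbon atom and if atom 1 is aromatic then kill")$items[[1]]
  out <- run_statement(st, benz_b, env0(), rxnforge:::new_outcome())
  expect_true(out$rating$killed)
  expect_length(out$trace, 1L)
  expect_true(out$trace[[1]]$fired)

  # aliphatic carbon: AND short-circuits, nothing fires
  eth_b <- find_matches(compile_pattern("[#6:1]"), mols[["ethane"]])[[1]]
  out2 <- run_statement(st, eth_b, env0(), rxnforge:::new_outcome())
  expect_false(out2$rating$killed)
  expect_false(out2$trace[[1]]$fired)

  # the amine1/amine2 lowering statement on a block with an off-path
  # primary amine: one MODERATELY delta, 50 - 10 = 40
  prog <- parse_program(paste(
    "if atom 1 is the origin of amine1 group",
    "or if atom 1 is the origin of amine2 group",
    "then lower rating moderately"))
  amine_b <- find_matches(compile_pattern("[NX3:1]"), mols[["benzylamine"]])[[1]]
  out3 <- run_program(prog, amine_b)
  expect_length(out3$rating$deltas, 1L)
  expect_equal(rating_value(out3$rating), 40L)
})

test_that("loops iterate matching objects in order; counts match brute force", {
  mols <- panel_mols()
  loop_src <- paste(
    "foreach carbon atom offpath defined as carbon_atom in molecule {",
    "if carbon_atom is aromatic then raise rating slightly }")
  prog <- parse_program(loop_src)

  # toluene with the methyl onpath: 6 offpath aromatic carbons -> 80
  tol_b <- find_matches(compile_pattern("[CH3:1]"), mols[["toluene"]])[[1]]
  out <- run_program(prog, tol_b)
  expect_length(out$rating$deltas, 6L)
  expect_equal(rating_value(out$rating), 80L)
  expect_length(out$trace, 6L)

  # ethane: one offpath carbon, not aromatic -> no deltas
  eth_b <- find_matches(compile_pattern("[CH3:1]"), mols[["ethane"]])[[1]]
  out2 <- run_program(prog, eth_b)
  expect_length(out2$rating$deltas, 0L)
  expect_equal(rating_value(out2$rating), 50L)
  expect_length(out2$trace, 1L)

  # empty iterand set: body never runs
  out3 <- run_program(parse_program(
    "foreach iodine atom defined as i_at in molecule { if i_at is aromatic then kill }"),
    eth_b)
  expect_length(out3$trace, 0L)
  expect_equal(rating_value(out3$rating), 50L)

  # loop-count law over the panel: body executions = brute-force object
  # counts for five iterand descriptors
  descriptors <- list(
    list(src = "foreach carbon atom defined as x in molecule { if x is aromatic then raise rating slightly }",
         count = function(m, b) sum(m$atoms$symbol == "C")),
    list(src = "foreach heteroatom defined as x in molecule { if x is aromatic then raise rating slightly }",
         count = function(m, b) sum(!(m$atoms$symbol %in% c("C", "H")))),
    list(src = "foreach atom offpath defined as x in molecule { if x is aromatic then raise rating slightly }",
         count = function(m, b) length(b$offpath_atoms)),
    list(src = "foreach bond defined as x in molecule { if x is aromatic then raise rating slightly }",
         count = function(m, b) nrow(m$bonds)),
    list(src = "foreach ring defined as x in rings { if x is aromatic then raise rating slightly }",
         count = function(m, b) length(m$rings)))
  cp <- compile_pattern("[#6:1]")
  panel <- panel_mols()
  with_c <- panel[vapply(panel, function(m) any(m$atoms$symbol == "C"), NA)]
  subset <- with_c[seq_len(20)]
  for (d in descriptors) {
    prog_d <- parse_program(d$src)
    for (m in subset) {
      b <- find_matches(cp, m)[[1]]
      out_d <- run_program(prog_d, b)
      expect_length(out_d$trace, d$count(m, b))
    }
  }
})

test_that("programs compose: kill short-circuits, deltas sum, clamping holds", {
  mols <- panel_mols()
  b <- find_matches(compile_pattern("[#6:1]"), mols[["benzene"]])[[1]]

  out <- run_program(parse_program(""), b)
  expect_equal(rating_value(out$rating), 50L)
  expect_false(out$rating$killed)
  expect_length(out$ghosts, 0L)

  # kill stops the program: the later raise never runs
  out2 <- run_program(parse_program(paste(
    "if atom 1 is aromatic then kill",
    "\nif atom 1 is aromatic then raise rating strongly")), b)
  expect_true(out2$rating$killed)
  expect_length(out2$rating$deltas, 0L)
  expect_length(out2$trace, 1L)

  # 50 + 5 - 20 = 35
  out3 <- run_program(parse_program(paste(
    "if atom 1 is aromatic then raise rating slightly",
    "\nif atom 1 is carbon atom then lower rating strongly")), b)
  expect_equal(rating_value(out3$rating), 35L)

  # ghost action attaches its fragment
  out4 <- run_program(parse_program(
    "if atom 1 is aromatic then ghost O"), b)
  expect_equal(out4$ghosts, "O")
})

test_that("random programs never leave [0, 100] and kills are monotone", {
  mols <- panel_mols()
  b <- iodo_binding()
  maps <- as.integer(names(b$atom_map))
  set.seed(1789)
  n_killed <- 0L
  for (k in 1:200) {
    prog <- gen_eval_program(maps, depth = 1L)
    out <- run_program(prog, b,
                       group_hits = list(amine1 = integer(),
                                         amine2 = integer(),
                                         carboxylic_acid = integer()))
    v <- rating_value(out$rating)
    expect_gte(v, 0L)
    expect_lte(v, 100L)
    n_killed <- n_killed + out$rating$killed

    # appending a raise can only increase (or preserve) the final value
    raised <- prog
    raised$items <- c(raised$items, parse_program(
      "if atom 1 is carbon atom then raise rating slightly")$items)
    out_r <- run_program(raised, b,
                         group_hits = list(amine1 = integer(),
                                           amine2 = integer(),
                                           carboxylic_acid = integer()))
    if (!out$rating$killed)
      expect_gte(rating_value(out_r$rating), v)
    # appending a kill never un-kills and never raises survival
    killed <- prog
    killed$items <- c(killed$items, parse_program(
      "if atom 1 is carbon atom then kill")$items)
    out_k <- run_program(killed, b,
                         group_hits = list(amine1 = integer(),
                                           amine2 = integer(),
                                           carboxylic_acid = integer()))
    expect_true(out_k$rating$killed)
  }
  expect_gt(n_killed, 0L)       # the generator does exercise kills
})
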