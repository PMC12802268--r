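# Screening, reaction application, enumeration, rating aggregation.

test_that("screening is pattern-only and counts compatible blocks", {
  t <- toy_transform_nologic()
  blocks <- lapply(
    c(iodobenzene = "Ic1ccccc1", iodotoluene = "Cc1ccc(I)cc1",
      phenol = "Oc1ccccc1", bromobenzene = "Brc1ccccc1",
      aniline = "Nc1ccccc1"),
    function(s) NULL)
  blocks <- Map(block_rec, names(blocks),
                c("Ic1ccccc1", "Cc1ccc(I)cc1", "Oc1ccccc1", "Brc1ccccc1",
                  "Nc1ccccc1"))
  scr <- screen_blocks(t, 1L, unname(blocks))
  expect_length(scr, 2L)
  expect_equal(vapply(scr, function(e) e$block$id, ""),
               c("iodobenzene", "iodotoluene"))

  acid <- rf_transform(id = "A", name = "acid slot", version = "1",
                       smirks = "[CX3:1](=[OX1:2])[OX2H1]>>[C:1]=[O:2]")
  scr2 <- screen_blocks(acid, 1L,
                        list(block_rec("a", "CC(=O)O"),
                             block_rec("b", "OC(=O)c1ccccc1"),
                             block_rec("c", "CCO")))
  expect_length(scr2, 2L)

  expect_length(screen_blocks(t, 1L, list()), 0L)
  expect_error(screen_blocks(t, 3L, list()), "out of range")
})

test_that("the mapped reaction builds the documented products", {
  suz <- stock_transform("suzuki")
  r <- apply_reaction(suz, list(
    list(block = block_rec("IB", "Ic1ccccc1")),
    list(block = block_rec("PBA", "OB(O)c1ccccc1"))))
  expect_equal(r$products, "c1ccc(-c2ccccc2)cc1")     # biphenyl
  expect_match(r$inchikeys, "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")

  acy <- stock_transform("acylsulfonamide")
  r2 <- apply_reaction(acy, list(
    list(block = block_rec("MSA", "CS(N)(=O)=O")),
    list(block = block_rec("ACA", "CC(=O)O"))))
  expect_equal(r2$products, "CC(=O)NS(C)(=O)=O")      # N-acetyl product
  expect_equal(r2$ghosts, "O")                        # water ghost
})

test_that("heavy atoms are conserved for the ghost-balanced condensation", {
  acy <- stock_transform("acylsulfonamide")
  combos <- list(c("CS(N)(=O)=O", "CC(=O)O"),
                 c("NS(=O)(=O)c1ccccc1", "OC(=O)c1ccccc1"),
                 c("CCS(N)(=O)=O", "CC(C)C(=O)O"))
  heavy <- function(smi) rf_parse_smiles(smi)[[1]]$n_atoms
  for (cmb in combos) {
    r <- apply_reaction(acy, list(list(block = block_rec("x", cmb[1])),
                                  list(block = block_rec("y", cmb[2]))))
    lhs <- heavy(cmb[1]) + heavy(cmb[2])
    rhs <- heavy(r$products[1]) + sum(vapply(r$ghosts, heavy, 0L))
    expect_equal(rhs, lhs, info = paste(cmb, collapse = " + "))
  }
})

test_that("combination rating is the minimum of the slot ratings", {
  expect_equal(combination_rating(c(50L, 50L)), 50L)
  expect_equal(combination_rating(c(80L, 35L)), 35L)
  expect_equal(combination_rating(c(0L, 90L)), 0L)
  expect_equal(combination_rating(55L), 55L)
  expect_error(combination_rating(integer()), "empty")
})

test_that("enumeration is exact combinatorics without logic", {
  t <- toy_transform_nologic()
  # substituent sets of the two slots are disjoint, so all biaryls differ
  b1 <- list(block_rec("i1", "Ic1ccc(F)cc1"),
             block_rec("i2", "Ic1ccc(OC)cc1"),
             block_rec("i3", "Ic1ccc(CC)cc1"))
  b2 <- list(block_rec("b1", "OB(O)c1ccccc1"),
             block_rec("b2", "OB(O)c1ccc(C)cc1"),
             block_rec("b3", "OB(O)c1ccc(CCC)cc1"),
             block_rec("b4", "OB(O)c1ccc(CCCC)cc1"))
  recs <- enumerate_products(t, list(b1, b2))
  expect_equal(nrow(recs), 12L)
  s <- attr(recs, "summary")
  expect_equal(s$slot_compatible, c(3L, 4L))
  expect_equal(s$slot_surviving, c(3L, 4L))
  expect_equal(s$combos_reacted, 12L)
  # deterministic slot-1-major order
  expect_equal(recs$r1_id, rep(c("i1", "i2", "i3"), each = 4L))
  expect_equal(recs$r2_id[1:4], c("b1", "b2", "b3", "b4"))
  expect_true(all(recs$rating == 50L))

  # slot-2 logic that kills one block's only binding: 3 x 3 = 9
  t2 <- rf_transform(
    id = "TOY2", name = "toy with veto", version = "1",
    smirks = "[c:1][I].[c:2][BX3]([OX2H])[OX2H]>>[c:1][c:2]",
    logic = c("", paste(
      "foreach chlorine atom offpath defined as cl in molecule {",
      "if cl is chlorine atom then kill }")))
  b2k <- c(b2[1:3], list(block_rec("b4cl", "OB(O)c1ccc(CCl)cc1")))
  recs2 <- enumerate_products(t2, list(b1, b2k))
  expect_equal(nrow(recs2), 9L)
  s2 <- attr(recs2, "summary")
  expect_equal(s2$slot_compatible, c(3L, 4L))    # screen stage unaffected
  expect_equal(s2$slot_surviving, c(3L, 3L))

  # a unimolecular transform degenerates correctly
  t1 <- rf_transform(id = "U", name = "deiodination", version = "1",
                     smirks = "[c:1][I]>>[c:1]")
  recs3 <- enumerate_products(t1, list(b1))
  expect_equal(nrow(recs3), 3L)
  expect_equal(names(recs3)[3], "r1_id")
})

test_that("dedupe collapses identical products under different parents", {
  t <- toy_transform_nologic()
  b1 <- list(block_rec("dup_a", "Ic1ccccc1"),
             block_rec("dup_b", "Ic1ccccc1"))
  b2 <- list(block_rec("b1", "OB(O)c1ccccc1"))
  recs <- enumerate_products(t, list(b1, b2))
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$r1_id, "dup_a")               # first seen wins
  expect_equal(attr(recs, "summary")$suppressed_duplicates, 1L)

  recs_nd <- enumerate_products(t, list(b1, b2),
                                generation_options(dedupe = FALSE))
  expect_equal(nrow(recs_nd), 2L)
})

test_that("kill filtering drops non-positive records unless disabled", {
  # lower severely twice: 50 - 35 - 35 -> clamped 0, non-positive
  t <- rf_transform(
    id = "K", name = "self-defeating", version = "1",
    smirks = "[c:1][I].[c:2][BX3]([OX2H])[OX2H]>>[c:1][c:2]",
    logic = c(paste(
      "if atom 1 is aromatic then lower rating severely",
      "\nif atom 1 is aromatic then lower rating severely"), ""))
  b1 <- list(block_rec("i1", "Ic1ccccc1"))
  b2 <- list(block_rec("b1", "OB(O)c1ccccc1"))
  recs <- enumerate_products(t, list(b1, b2))
  expect_equal(nrow(recs), 0L)
  expect_equal(attr(recs, "summary")$slot_surviving, c(0L, 1L))

  recs2 <- enumerate_products(t, list(b1, b2),
                              generation_options(kill_low_rated = FALSE))
  expect_equal(nrow(recs2), 1L)
  expect_equal(recs2$rating, 0L)
})

test_that("screen count bounds survivor count on fixture runs", {
  suz <- stock_transform("suzuki")
  f1 <- make_fixtures(301, 8, "aryl_iodide")
  f2 <- make_fixtures(302, 8, "boronic_acid")
  blocks <- list(read_blocks(f1), read_blocks(f2))
  recs <- enumerate_products(suz, blocks)
  s <- attr(recs, "summary")
  expect_true(all(s$slot_surviving <= s$slot_compatible))
  # count bound: emitted records never exceed the survivor product
  expect_lte(nrow(recs), prod(s$slot_surviving))
})

test_that("enumeration streams deterministically and in parallel", {
  suz <- stock_transform("suzuki")
  f1 <- make_fixtures(41, 6, "aryl_iodide")
  f2 <- make_fixtures(42, 6, "boronic_acid")
  blocks <- list(read_blocks(f1), read_blocks(f2))
  r1 <- enumerate_products(suz, blocks)
  r2 <- enumerate_products(suz, blocks)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  # 4-worker partitioned run equals the serial product set, in order
  r4 <- enumerate_products(suz, blocks,
                           generation_options(workers = 4L, chunk_size = 7L))
  expect_identical(as.data.frame(r4), as.data.frame(r1))

  # max_products caps the stream
  rc <- enumerate_products(suz, blocks,
                           generation_options(max_products = 5))
  expect_equal(nrow(rc), 5L)
  expect_equal(rc$inchikey, r1$inchikey[1:5])
  expect_equal(rc$r1_id, r1$r1_id[1:5])
})
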