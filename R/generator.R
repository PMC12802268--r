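## Product generation: screen building blocks per reactant slot, evaluate
## slot logic, enumerate the Cartesian product of survivors in
## deterministic file order, apply the mapped reaction, and emit rated,
## ghost-balanced product records.
##
## Staged accounting mirrors the two-stage bookkeeping of the transform
## engine: "compatible" counts are pattern-only (before the logic check);
## surviving counts come after logic; products are retained only with a
## positive, unkilled score (unless kill filtering is disabled).

#' Generation options
#'
#' @param hide_ghosts Suppress ghost fragments from written outputs.
#' @param kill_low_rated Drop killed and non-positively rated combinations
#'   (the "positive scoring" retention rule).
#' @param inchikey_only Write only an InChIKey-per-line text file.
#' @param dedupe Collapse records with the same product InChIKey
#'   (first seen wins; parents and ghosts are not part of the key).
#' @param max_products Optional cap on emitted records.
#' @param random_seed Seed recorded for any sampling mode (enumeration
#'   itself is deterministic).
#' @param workers Partition slot-1 blocks over this many processes; the
#'   merged output equals the serial run.
#' @param chunk_size Reactions sent to the host toolkit per batch.
#' @return A \code{rf_options} list.
#' @export
generation_options <- function(hide_ghosts = FALSE, kill_low_rated = TRUE,
                               inchikey_only = FALSE, dedupe = TRUE,
                               max_products = Inf, random_seed = 1L,
                               workers = 1L, chunk_size = 20000L) {
  structure(list(hide_ghosts = hide_ghosts, kill_low_rated = kill_low_rated,
                 inchikey_only = inchikey_only, dedupe = dedupe,
                 max_products = max_products, random_seed = random_seed,
                 workers = as.integer(workers),
                 chunk_size = as.integer(chunk_size)),
            class = "rf_options")
}

#' Screen building blocks against one reactant slot
#'
#' Pattern matching only -- logic is not applied at this stage, so the
#' returned count is the "compatible reactant" figure of the staged
#' accounting.
#'
#' @param t An \code{rf_transform}.
#' @param slot Reactant slot index.
#' @param blocks A block list from \code{\link{read_blocks}} (or any list
#'   of \code{list(id=, smiles=, mol=)} records).
#' @return List of \code{list(block=, bindings=)} for blocks with at least
#'   one match, in input order.
#' @export
screen_blocks <- function(t, slot, blocks) {
  stopifnot(inherits(t, "rf_transform"))
  if (slot < 1L || slot > length(t$reaction$reactant_smarts))
    stop("slot ", slot, " out of range")
  if (!length(blocks)) return(list())
  p <- compile_pattern(t$reaction$reactant_smarts[slot])
  mols <- lapply(blocks, `[[`, "mol")
  all_bindings <- find_matches_many(p, mols)
  out <- list()
  for (k in seq_along(blocks)) {
    if (length(all_bindings[[k]]))
      out[[length(out) + 1L]] <- list(block = blocks[[k]],
                                      bindings = all_bindings[[k]])
  }
  out
}

slot_program <- function(t, slot) {
  if (slot <= length(t$reactant_logic)) t$reactant_logic[[slot]]$program
  else structure(list(kind = "program", items = list()),
                 class = "rf_program")
}

## run slot logic over screened blocks; group hits are resolved in one
## worker round trip per referenced group
evaluate_slot <- function(t, slot, screened, groups = default_group_library(),
                          collect_trace = FALSE) {
  prog <- slot_program(t, slot)
  grefs <- program_group_refs(prog)
  mols <- lapply(screened, function(e) e$block$mol)
  hits_by_group <- lapply(grefs, function(g) group_hits_many(groups, g, mols))
  names(hits_by_group) <- grefs
  lapply(seq_along(screened), function(k) {
    e <- screened[[k]]
    gh <- lapply(hits_by_group, `[[`, k)
    outcomes <- lapply(e$bindings, function(b)
      run_program(prog, b, groups, group_hits = gh))
    vals <- vapply(outcomes, function(o) rating_value(o$rating), 0L)
    killed <- vapply(outcomes, function(o) o$rating$killed, NA)
    surviving <- which(!killed & vals > 0L)
    best <- if (length(surviving)) {
      ## highest rating; ties broken towards the lowest matched atom indices
      cand <- surviving[vals[surviving] == max(vals[surviving])]
      keys <- vapply(cand, function(i)
        paste(sprintf("%06d", sort(e$bindings[[i]]$onpath_atoms)),
              collapse = ","), "")
      cand[order(keys)][1]
    } else {
      which.max(vals - killed * 1000L)     # best effort for no-kill mode
    }
    list(block = e$block, binding = e$bindings[[best]],
         rating = vals[best], killed = length(surviving) == 0L,
         ghosts = outcomes[[best]]$ghosts,
         trace = if (collect_trace) outcomes[[best]]$trace else NULL)
  })
}

#' Aggregate per-slot ratings into a product rating
#'
#' The minimum rule: a combination is as favorable as its worst slot.
#'
#' @param slot_ratings Integer vector, one rating per reactant slot.
#' @return Integer rating.
#' @export
combination_rating <- function(slot_ratings) {
  if (!length(slot_ratings)) stop("combination_rating: empty rating list")
  stopifnot(all(slot_ratings >= 0L & slot_ratings <= 100L))
  min(slot_ratings)
}

#' Apply the mapped reaction to one chosen combination
#'
#' @param t An \code{rf_transform}.
#' @param chosen List with one \code{list(block=, binding=)} per slot.
#' @return \code{list(products=, inchikeys=, ghosts=,
#'   n_sanitize_failures=)}; products are canonical SMILES (symmetric match
#'   sites deduplicated), ghosts are the transform's declared templates.
#' @export
apply_reaction <- function(t, chosen) {
  combo <- lapply(chosen, function(e) e$block$smiles)
  res <- bridge_call("react", smirks = t$reaction$smirks,
                     combos = list(combo), inchikey = TRUE)[[1]]
  if (!isTRUE(res$ok)) stop("reaction failed: ", res$error)
  list(products = as.character(unlist(res$products)),
       inchikeys = as.character(unlist(res$inchikeys)),
       ghosts = t$ghost_templates,
       n_sanitize_failures = as.integer(res$n_sanitize_failures))
}

## combo grid in deterministic order: slot 1 slowest (outer loop, file
## order), last slot fastest
combo_grid <- function(lengths) {
  if (any(lengths == 0L)) return(matrix(integer(), ncol = length(lengths)))
  g <- do.call(expand.grid, rev(lapply(lengths, seq_len)))
  as.matrix(g[, rev(seq_along(lengths)), drop = FALSE])
}

## turn one batch of combos into record rows (no dedupe/cap here)
react_batch <- function(t, entries_by_slot, grid_rows, ratings, killed,
                        ghosts_chr, chunk_size) {
  n_slots <- length(entries_by_slot)
  recs <- list()
  n_fail <- 0L
  rows <- seq_len(nrow(grid_rows))
  for (start in seq(1L, length(rows), by = chunk_size)) {
    idx <- rows[start:min(start + chunk_size - 1L, length(rows))]
    combos <- lapply(idx, function(r)
      lapply(seq_len(n_slots), function(s)
        entries_by_slot[[s]][[grid_rows[r, s]]]$block$smiles))
    res <- bridge_call("react", smirks = t$reaction$smirks,
                       combos = combos, inchikey = TRUE)
    for (j in seq_along(idx)) {
      r <- idx[j]
      rj <- res[[j]]
      if (!isTRUE(rj$ok)) { n_fail <- n_fail + 1L; next }
      n_fail <- n_fail + as.integer(rj$n_sanitize_failures)
      prods <- as.character(unlist(rj$products))
      keys <- as.character(unlist(rj$inchikeys))
      ids <- vapply(seq_len(n_slots), function(s)
        entries_by_slot[[s]][[grid_rows[r, s]]]$block$id, "")
      for (q in seq_along(prods)) {
        recs[[length(recs) + 1L]] <-
          c(list(product_smiles = prods[q], inchikey = keys[q]),
            stats::setNames(as.list(ids), paste0("r", seq_len(n_slots), "_id")),
            list(rating = ratings[r], killed = killed[r],
                 ghosts = ghosts_chr[r]))
      }
    }
  }
  list(records = recs, n_fail = n_fail)
}

records_to_df <- function(recs, n_slots) {
  cols <- c("product_smiles", "inchikey",
            paste0("r", seq_len(n_slots), "_id"), "rating", "killed",
            "ghosts")
  if (!length(recs)) {
    df <- as.data.frame(stats::setNames(
      lapply(cols, function(cl)
        if (cl == "rating") integer() else if (cl == "killed") logical()
        else character()), cols), stringsAsFactors = FALSE)
    return(df)
  }
  df <- do.call(rbind, lapply(recs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  df[, cols]
}

#' Enumerate a virtual product library
#'
#' Screens each slot's blocks (pattern only), runs the slot logic, walks
#' the Cartesian product of survivors in deterministic file order, applies
#' the mapped reaction in batches, and collects rated product records.
#' Combination rating is the minimum of the slot ratings; combinations with
#' a killed or non-positive slot are dropped when \code{kill_low_rated} is
#' on.  Deduplication is by product InChIKey, first seen wins.
#'
#' @param t An \code{rf_transform}.
#' @param blocks_by_slot List with one block list per reactant slot.
#' @param opts \code{\link{generation_options}}.
#' @param groups Group library for logic evaluation.
#' @param collect_trace Keep per-block statement traces in the summary.
#' @return A data frame of product records (class \code{rf_products}) with
#'   a \code{summary} attribute carrying the staged accounting counts.
#' @export
enumerate_products <- function(t, blocks_by_slot,
                               opts = generation_options(),
                               groups = default_group_library(),
                               collect_trace = FALSE) {
  stopifnot(inherits(t, "rf_transform"))
  n_slots <- length(t$reaction$reactant_smarts)
  if (length(blocks_by_slot) != n_slots)
    stop("need one block list per reactant slot (", n_slots, ")")
  screened <- lapply(seq_len(n_slots), function(s)
    screen_blocks(t, s, blocks_by_slot[[s]]))
  evaluated <- lapply(seq_len(n_slots), function(s)
    evaluate_slot(t, s, screened[[s]], groups, collect_trace))
  surviving <- lapply(evaluated, function(ev)
    Filter(function(e) !e$killed && e$rating > 0L, ev))
  use <- if (opts$kill_low_rated) surviving else evaluated
  lens <- vapply(use, length, 0L)
  grid <- combo_grid(lens)
  n_combos_total <- prod(vapply(screened, length, 0L) *
                           (vapply(screened, length, 0L) > 0L))
  ratings <- killed <- NULL
  if (nrow(grid)) {
    rmat <- vapply(seq_len(n_slots), function(s)
      vapply(use[[s]], `[[`, 0L, "rating")[grid[, s]],
      integer(nrow(grid)))
    kmat <- vapply(seq_len(n_slots), function(s)
      vapply(use[[s]], `[[`, NA, "killed")[grid[, s]],
      logical(nrow(grid)))
    if (nrow(grid) == 1L) { rmat <- matrix(rmat, 1L); kmat <- matrix(kmat, 1L) }
    ratings <- as.integer(apply(rmat, 1L, min))
    killed <- apply(kmat, 1L, any)
    ghosts_chr <- vapply(seq_len(nrow(grid)), function(r)
      paste(unique(c(t$ghost_templates,
                     unlist(lapply(seq_len(n_slots), function(s)
                       use[[s]][[grid[r, s]]]$ghosts)))), collapse = ";"),
      "")
    if (opts$kill_low_rated) {
      keep <- which(!killed & ratings > 0L)
      grid <- grid[keep, , drop = FALSE]
      ratings <- ratings[keep]; killed <- killed[keep]
      ghosts_chr <- ghosts_chr[keep]
    }
  } else ghosts_chr <- character()

  n_fail <- 0L
  if (nrow(grid) == 0L) {
    df <- records_to_df(list(), n_slots)
  } else if (opts$workers > 1L) {
    ranges <- parallel::splitIndices(nrow(grid), opts$workers)
    parts <- parallel::mclapply(ranges, function(ix) {
      react_batch(t, use, grid[ix, , drop = FALSE], ratings[ix],
                  killed[ix], ghosts_chr[ix], opts$chunk_size)
    }, mc.cores = opts$workers)
    n_fail <- sum(vapply(parts, `[[`, 0L, "n_fail"))
    df <- records_to_df(do.call(c, lapply(parts, `[[`, "records")), n_slots)
  } else {
    rb <- react_batch(t, use, grid, ratings, killed, ghosts_chr,
                      opts$chunk_size)
    n_fail <- rb$n_fail
    df <- records_to_df(rb$records, n_slots)
  }
  n_before_dedupe <- nrow(df)
  if (opts$dedupe && nrow(df))
    df <- df[!duplicated(df$inchikey), , drop = FALSE]
  n_dupes <- n_before_dedupe - nrow(df)
  n_capped <- 0L
  if (is.finite(opts$max_products) && nrow(df) > opts$max_products) {
    n_capped <- nrow(df) - as.integer(opts$max_products)
    df <- df[seq_len(opts$max_products), , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "summary") <- list(
    slot_compatible = vapply(screened, length, 0L),
    slot_surviving = vapply(surviving, length, 0L),
    combos_total = n_combos_total,
    combos_reacted = nrow(grid),
    emitted = nrow(df),
    killed_emitted = sum(df$killed),
    suppressed_duplicates = n_dupes,
    capped = n_capped,
    sanitize_failures = n_fail,
    trace = if (collect_trace) lapply(seq_len(n_slots), function(s)
      lapply(evaluated[[s]], function(e)
        list(block_id = e$block$id, trace = e$trace))) else NULL)
  class(df) <- c("rf_products", "data.frame")
  df
}

#' @export
print.rf_products <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<rf_products> ", nrow(x), " record(s)\n", sep = "")
  if (!is.null(s)) {
    cat("  compatible per slot: ", paste(s$slot_compatible, collapse = " x "),
        "; surviving after logic: ",
        paste(s$slot_surviving, collapse = " x "), "\n", sep = "")
    cat("  combinations reacted: ", s$combos_reacted,
        "; duplicates suppressed: ", s$suppressed_duplicates,
        "; sanitize failures: ", s$sanitize_failures, "\n", sep = "")
  }
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}
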