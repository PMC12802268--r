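## Transform model and lossless (de)serialization of the two on-disk
## dialects: `.slice` (XML, human-oriented) and `.jslice` (JSON,
## engine-oriented).  Logic is stored as text inside the file and parsed at
## load time, so files stay readable and syntax errors surface immediately.
##
## Neither dialect's element/key names are published by the upstream
## project; the element set written here is this package's own documented,
## stable schema (see the methods vignette).  Exact file-level
## compatibility with other tools is not claimed.

METRIC_NAMES <- c("yield", "reliability", "reputation", "homoselectivity",
                  "heteroselectivity", "orientational_selectivity",
                  "condition_flexibility", "thermodynamics")

## split a SMIRKS side on top-level "." (never inside [] or ())
split_components <- function(s) {
  depth <- 0L
  cuts <- integer()
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% c("[", "(")) depth <- depth + 1L
    else if (ch %in% c("]", ")")) depth <- depth - 1L
    else if (ch == "." && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts), function(k)
    paste(chars[starts[k]:ends[k]], collapse = ""), "")
}

#' Construct a reaction transform
#'
#' A transform bundles one reaction type: identifying metadata, optional
#' quality metrics, an atom-mapped reaction pattern, one logic program per
#' reactant slot, and ghost templates (small fragments emitted to balance
#' the reaction formally).
#'
#' @param id,name,version Mandatory identity strings (non-empty).
#' @param smirks Atom-mapped reaction SMARTS, `reactants>>product`.
#' @param reactant_smarts Per-slot keying SMARTS (possibly carrying the
#'   package's SMARTS extensions); derived by splitting \code{smirks} when
#'   omitted.
#' @param product_smarts Product-side SMARTS; derived from \code{smirks}
#'   when omitted.
#' @param logic Character vector of logic source blocks, one per reactant
#'   slot ("" for unconstrained slots); parsed immediately and stored in
#'   canonical form.
#' @param ghosts Character vector of ghost fragment SMILES attached to
#'   every product of the transform.
#' @param metrics Named numeric vector; names from
#'   yield, reliability, reputation, homoselectivity, heteroselectivity,
#'   orientational_selectivity, condition_flexibility, thermodynamics;
#'   values on a 0--100 scale.  All optional.
#' @param history List of \code{list(timestamp=, note=)} records
#'   (append-only; see \code{\link{rf_add_history}}).
#' @param references Character vector of free-text bibliography entries.
#' @param comments,conditions Free text.
#' @return An \code{rf_transform}.
#' @export
rf_transform <- function(id, name, version, smirks,
                         reactant_smarts = NULL, product_smarts = NULL,
                         logic = character(), ghosts = character(),
                         metrics = numeric(), history = list(),
                         references = character(), comments = "",
                         conditions = "") {
  sides <- strsplit(smirks, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("SMIRKS must have exactly one '>>': ", smirks)
  if (is.null(reactant_smarts)) reactant_smarts <- split_components(sides[1])
  if (is.null(product_smarts)) product_smarts <- sides[2]
  metrics <- if (length(metrics)) {
    v <- as.numeric(metrics)
    names(v) <- names(metrics)
    v
  } else numeric()
  logic <- as.character(logic)
  programs <- lapply(logic, function(txt)
    if (nzchar(trimws(txt))) parse_program(txt) else
      structure(list(kind = "program", items = list()), class = "rf_program"))
  t <- structure(list(
    meta = list(id = as.character(id), name = as.character(name),
                version = as.character(version), history = history,
                references = as.character(references),
                comments = as.character(comments),
                conditions = as.character(conditions)),
    metrics = metrics,
    reaction = list(smirks = smirks,
                    reactant_smarts = as.character(reactant_smarts),
                    product_smarts = as.character(product_smarts)),
    reactant_logic = lapply(programs, function(pr)
      list(text = serialize_program(pr), program = pr)),
    ghost_templates = as.character(ghosts)),
    class = "rf_transform")
  t
}

#' @export
print.rf_transform <- function(x, ...) {
  cat("<rf_transform> ", x$meta$id, " '", x$meta$name, "' v",
      x$meta$version, "\n", sep = "")
  cat("  reaction: ", x$reaction$smirks, "\n", sep = "")
  cat("  slots: ", length(x$reaction$reactant_smarts),
      ", logic blocks: ", length(x$reactant_logic),
      ", ghosts: ", length(x$ghost_templates), "\n", sep = "")
  invisible(x)
}

#' Append a history event to a transform
#'
#' History is append-only: edits to a transform go through helpers that
#' record what changed and never rewrite past entries.
#'
#' @param t An \code{rf_transform}.
#' @param note Free-text description of the change.
#' @param timestamp Override the recorded time (ISO-8601 string).
#' @return The modified transform.
#' @export
rf_add_history <- function(t, note,
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  stopifnot(inherits(t, "rf_transform"))
  t$meta$history <- c(t$meta$history,
                      list(list(timestamp = timestamp, note = note)))
  t
}

## ---- validation -----------------------------------------------------------

diag_row <- function(severity, location, message)
  data.frame(severity = severity, location = location, message = message,
             stringsAsFactors = FALSE)

smarts_map_nums <- function(smarts_vec) {
  core <- vapply(smarts_vec, function(s) compile_pattern(s)$core_smarts, "")
  info <- bridge_call("smarts_info", smarts = as.list(core))
  lapply(info, function(x) {
    if (!isTRUE(x$ok)) return(x$error)
    mn <- as.integer(unlist(x$map_nums))
    mn[mn > 0L]
  })
}

#' Validate a transform
#'
#' Checks every structural invariant: mandatory identity fields, metric
#' bounds, SMARTS/SMIRKS compilability, atom-map cross-references between
#' logic and the keying patterns, reactant-side coverage of product-side
#' maps, ghost template parseability, and (as warnings) group names not
#' present in the group library.
#'
#' @param t An \code{rf_transform}.
#' @param groups A group library (see \code{\link{read_group_library}});
#'   defaults to the library shipped with the package.
#' @return A data frame of diagnostics (severity, location, message);
#'   zero rows for a fully valid transform.
#' @export
validate_transform <- function(t, groups = default_group_library()) {
  d <- diag_row(character(), character(), character())
  for (f in c("id", "name", "version")) {
    if (!nzchar(t$meta[[f]]))
      d <- rbind(d, diag_row("error", paste0("meta/", f),
                             paste0("mandatory field '", f, "' is empty")))
  }
  if (length(t$metrics)) {
    bad_names <- setdiff(names(t$metrics), METRIC_NAMES)
    for (b in bad_names)
      d <- rbind(d, diag_row("error", paste0("metrics/", b),
                             paste0("unknown metric '", b, "'")))
    for (m in intersect(names(t$metrics), METRIC_NAMES)) {
      v <- t$metrics[[m]]
      if (!is.finite(v) || v < 0 || v > 100)
        d <- rbind(d, diag_row("error", paste0("metrics/", m),
                               paste0("metric '", m, "' = ", v,
                                      " outside [0, 100]")))
    }
  }
  n_slots <- length(t$reaction$reactant_smarts)
  if (length(t$reactant_logic) > n_slots)
    d <- rbind(d, diag_row("error", "logic",
                           paste0(length(t$reactant_logic),
                                  " logic blocks for ", n_slots,
                                  " reactant slots")))
  ## compile patterns and collect map numbers
  maps <- tryCatch(
    smarts_map_nums(c(t$reaction$reactant_smarts,
                      t$reaction$product_smarts)),
    error = function(e) e$message)
  if (is.character(maps) && length(maps) == 1L) {
    d <- rbind(d, diag_row("error", "pattern", maps))
    return(d)
  }
  slot_maps <- maps[seq_len(n_slots)]
  prod_maps <- maps[[n_slots + 1L]]
  for (k in seq_along(maps)) {
    if (is.character(maps[[k]]))
      d <- rbind(d, diag_row("error",
                             if (k <= n_slots) paste0("pattern/reactant", k)
                             else "pattern/product", maps[[k]]))
  }
  ok_maps <- !vapply(maps, is.character, NA)
  if (all(ok_maps)) {
    all_reactant_maps <- sort(unique(unlist(slot_maps)))
    missing_prod <- setdiff(prod_maps, all_reactant_maps)
    if (length(missing_prod))
      d <- rbind(d, diag_row("error", "pattern/product",
                             paste0("product-side atom map(s) ",
                                    paste(missing_prod, collapse = ", "),
                                    " have no reactant-side counterpart")))
    for (k in seq_along(t$reactant_logic)) {
      refs <- program_atom_refs(t$reactant_logic[[k]]$program)
      bad <- setdiff(refs, slot_maps[[k]])
      if (length(bad))
        d <- rbind(d, diag_row("error", paste0("logic/reactant", k),
                               paste0("logic references atom map(s) ",
                                      paste(bad, collapse = ", "),
                                      " not present in the slot's keying pattern")))
      grefs <- program_group_refs(t$reactant_logic[[k]]$program)
      unknown <- setdiff(grefs, names(groups))
      if (length(unknown))
        d <- rbind(d, diag_row("warning", paste0("logic/reactant", k),
                               paste0("group name(s) not in the group library: ",
                                      paste(unknown, collapse = ", "))))
    }
  }
  if (length(t$ghost_templates)) {
    mols <- rf_parse_smiles(t$ghost_templates)
    for (k in seq_along(mols)) {
      if (is.null(mols[[k]]))
        d <- rbind(d, diag_row("error", paste0("ghosts/", k),
                               paste0("ghost template is not valid SMILES: ",
                                      t$ghost_templates[[k]])))
    }
  }
  d
}

assert_valid_transform <- function(t, groups = default_group_library()) {
  d <- validate_transform(t, groups)
  errs <- d[d$severity == "error", , drop = FALSE]
  if (nrow(errs))
    stop("invalid transform:\n",
         paste0("  [", errs$location, "] ", errs$message, collapse = "\n"))
  invisible(t)
}

## ---- XML dialect ----------------------------------------------------------

transform_to_xml <- function(t) {
  doc <- xml2::xml_new_root("transform", id = t$meta$id,
                            version = t$meta$version)
  desc <- xml2::xml_add_child(doc, "description")
  xml2::xml_add_child(desc, "name", t$meta$name)
  hist <- xml2::xml_add_child(desc, "history")
  for (h in t$meta$history)
    xml2::xml_add_child(hist, "event", timestamp = h$timestamp,
                        note = h$note)
  refs <- xml2::xml_add_child(desc, "references")
  for (r in t$meta$references) xml2::xml_add_child(refs, "reference", r)
  xml2::xml_add_child(desc, "comments", t$meta$comments)
  mets <- xml2::xml_add_child(doc, "metrics")
  for (m in names(t$metrics))
    xml2::xml_add_child(mets, "metric", name = m,
                        value = format(t$metrics[[m]]))
  pat <- xml2::xml_add_child(doc, "pattern")
  xml2::xml_add_child(pat, "smirks", t$reaction$smirks)
  for (k in seq_along(t$reaction$reactant_smarts))
    xml2::xml_add_child(pat, "reactant", index = as.character(k),
                        smarts = t$reaction$reactant_smarts[k])
  xml2::xml_add_child(pat, "product", smarts = t$reaction$product_smarts)
  xml2::xml_add_child(doc, "conditions", t$meta$conditions)
  for (k in seq_along(t$reactant_logic))
    xml2::xml_add_child(doc, "logic", reactant = as.character(k),
                        t$reactant_logic[[k]]$text)
  gh <- xml2::xml_add_child(doc, "ghosts")
  for (g in t$ghost_templates)
    xml2::xml_add_child(gh, "ghost", smiles = g)
  doc
}

xml_text1 <- function(node, xpath) {
  n <- xml2::xml_find_first(node, xpath)
  if (inherits(n, "xml_missing")) "" else xml2::xml_text(n)
}

transform_from_xml <- function(doc, path = "<xml>") {
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "transform")
    stop("format error in ", path, ": root element is <",
         xml2::xml_name(root), ">, expected <transform>")
  pat <- xml2::xml_find_first(root, "./pattern")
  if (inherits(pat, "xml_missing"))
    stop("format error in ", path, ": missing <pattern> element")
  smirks <- xml_text1(pat, "./smirks")
  if (!nzchar(smirks))
    stop("format error in ", path, ": missing <smirks> inside <pattern>")
  rnodes <- xml2::xml_find_all(pat, "./reactant")
  r_idx <- as.integer(xml2::xml_attr(rnodes, "index"))
  r_smarts <- xml2::xml_attr(rnodes, "smarts")[order(r_idx)]
  hist <- lapply(xml2::xml_find_all(root, "./description/history/event"),
                 function(e) list(timestamp = xml2::xml_attr(e, "timestamp"),
                                  note = xml2::xml_attr(e, "note")))
  mnodes <- xml2::xml_find_all(root, "./metrics/metric")
  metrics <- as.numeric(xml2::xml_attr(mnodes, "value"))
  names(metrics) <- xml2::xml_attr(mnodes, "name")
  lnodes <- xml2::xml_find_all(root, "./logic")
  l_idx <- as.integer(xml2::xml_attr(lnodes, "reactant"))
  logic <- character(length(r_smarts))
  for (k in seq_along(lnodes)) {
    i <- l_idx[k]
    if (is.na(i) || i < 1L || i > length(logic))
      stop("format error in ", path, ": <logic reactant='",
           xml2::xml_attr(lnodes[[k]], "reactant"),
           "'> does not name a reactant slot")
    logic[i] <- xml2::xml_text(lnodes[[k]])
  }
  rf_transform(
    id = xml2::xml_attr(root, "id"),
    name = xml_text1(root, "./description/name"),
    version = xml2::xml_attr(root, "version"),
    smirks = smirks,
    reactant_smarts = if (length(r_smarts)) r_smarts else NULL,
    product_smarts = {
      pn <- xml2::xml_find_first(pat, "./product")
      if (inherits(pn, "xml_missing")) NULL else xml2::xml_attr(pn, "smarts")
    },
    logic = logic,
    ghosts = xml2::xml_attr(xml2::xml_find_all(root, "./ghosts/ghost"),
                            "smiles"),
    metrics = metrics,
    history = hist,
    references = xml2::xml_text(
      xml2::xml_find_all(root, "./description/references/reference")),
    comments = xml_text1(root, "./description/comments"),
    conditions = xml_text1(root, "./conditions"))
}

## ---- JSON dialect ---------------------------------------------------------

transform_to_json <- function(t) {
  obj <- list(
    id = t$meta$id, name = t$meta$name, version = t$meta$version,
    history = lapply(t$meta$history, function(h)
      list(timestamp = h$timestamp, note = h$note)),
    references = as.list(t$meta$references),
    comments = t$meta$comments,
    conditions = t$meta$conditions,
    metrics = as.list(t$metrics),
    pattern = list(smirks = t$reaction$smirks,
                   reactants = as.list(t$reaction$reactant_smarts),
                   product = t$reaction$product_smarts),
    logic = as.list(vapply(t$reactant_logic, `[[`, "", "text")),
    ghosts = as.list(t$ghost_templates))
  jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

transform_from_json <- function(obj, path = "<json>") {
  need <- function(key) {
    if (is.null(obj[[key]]))
      stop("format error in ", path, ": missing key '", key, "'")
    obj[[key]]
  }
  pat <- need("pattern")
  if (is.null(pat$smirks))
    stop("format error in ", path, ": missing key 'pattern/smirks'")
  rf_transform(
    id = need("id"), name = need("name"), version = need("version"),
    smirks = pat$smirks,
    reactant_smarts = if (length(pat$reactants))
      as.character(unlist(pat$reactants)) else NULL,
    product_smarts = pat$product,
    logic = if (length(obj$logic)) as.character(unlist(obj$logic))
            else character(),
    ghosts = if (length(obj$ghosts)) as.character(unlist(obj$ghosts))
             else character(),
    metrics = if (length(obj$metrics)) unlist(obj$metrics) else numeric(),
    history = if (length(obj$history))
      lapply(obj$history, function(h)
        list(timestamp = h$timestamp, note = h$note)) else list(),
    references = if (length(obj$references))
      as.character(unlist(obj$references)) else character(),
    comments = if (is.null(obj$comments)) "" else obj$comments,
    conditions = if (is.null(obj$conditions)) "" else obj$conditions)
}

## ---- read / write ---------------------------------------------------------

resolve_dialect <- function(path, dialect) {
  if (dialect != "auto") return(dialect)
  ext <- tolower(tools::file_ext(path))
  if (ext == "slice") return("xml")
  if (ext == "jslice") return("json")
  stop("cannot infer dialect from extension '.", ext,
       "'; pass dialect='xml' or 'json'")
}

#' Read a transform file
#'
#' @param path Path to a \code{.slice} (XML) or \code{.jslice} (JSON) file.
#' @param dialect \code{"xml"}, \code{"json"}, or \code{"auto"} (resolve
#'   from the extension).
#' @param validate Raise an error on any validation error (default TRUE).
#' @return An \code{rf_transform}.  Logic blocks are parsed at load time, so
#'   syntax errors surface immediately with file context.
#' @export
read_transform <- function(path, dialect = c("auto", "xml", "json"),
                           validate = TRUE) {
  dialect <- resolve_dialect(path, match.arg(dialect))
  if (!file.exists(path)) stop("transform file not found: ", path)
  t <- if (dialect == "xml") {
    doc <- tryCatch(xml2::read_xml(path), error = function(e)
      stop("format error in ", path, ": ", conditionMessage(e)))
    transform_from_xml(doc, path)
  } else {
    obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e)
                      stop("format error in ", path, ": ",
                           conditionMessage(e)))
    transform_from_json(obj, path)
  }
  if (validate) assert_valid_transform(t)
  t
}

#' Write a transform file
#'
#' The two dialects are semantically identical; writing and re-reading a
#' valid transform through either is an exact fixpoint.
#'
#' @param t An \code{rf_transform} (validated before writing).
#' @param path Output path.
#' @param dialect \code{"xml"}, \code{"json"}, or \code{"auto"}.
#' @return \code{path}, invisibly.
#' @export
write_transform <- function(t, path, dialect = c("auto", "xml", "json")) {
  stopifnot(inherits(t, "rf_transform"))
  dialect <- resolve_dialect(path, match.arg(dialect))
  assert_valid_transform(t)
  if (dialect == "xml") {
    xml2::write_xml(transform_to_xml(t), path)
  } else {
    writeLines(transform_to_json(t), path)
  }
  invisible(path)
}
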