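## The transform logic language: lexer, recursive-descent parser, AST,
## canonical serializer.
##
## The language is a small IFTTT-style rule dialect evaluated per pattern
## match:
##
##   if <subject> <relation> <predicate> <where> then <action>
##   foreach <entity> <where> defined as <var> in <container> { ... }
##   define set <name> as <entity> <where>
##
## Statements chain with "and if" / "or if" (strict left-to-right,
## left-associative, short-circuiting).  Subjects and predicates chain with
## plain "and" / "or".  Keywords are case-insensitive, "//" comments run to
## end of line, and newlines are ordinary whitespace.

ELEMENTS <- c(carbon = "C", nitrogen = "N", oxygen = "O", sulfur = "S",
              sulphur = "S", phosphorus = "P", fluorine = "F",
              chlorine = "Cl", bromine = "Br", iodine = "I", boron = "B",
              silicon = "Si", selenium = "Se")

NUMBER_WORDS <- c(zero = 0L, one = 1L, two = 2L, three = 3L, four = 4L,
                  five = 5L, six = 6L, seven = 7L, eight = 8L, nine = 9L,
                  ten = 10L)

.KEYWORDS <- c(
  "if" = "IF", "then" = "THEN", "and" = "AND", "or" = "OR",
  "is" = "IS", "are" = "IS", "has" = "HAS", "have" = "HAS",
  "not" = "NOT", "kill" = "KILL", "raise" = "RAISE", "lower" = "LOWER",
  "rating" = "RATING", "foreach" = "FOREACH", "in" = "IN", "of" = "OF",
  "offpath" = "OFFPATH", "onpath" = "ONPATH",
  "atom" = "ATOM", "atoms" = "ATOMS", "bond" = "BOND", "bonds" = "BONDS",
  "between" = "BETWEEN", "molecule" = "MOLECULE",
  "exactly" = "EXACTLY", "ghost" = "GHOST",
  "slightly" = "SLIGHTLY", "moderately" = "MODERATELY",
  "strongly" = "STRONGLY", "severely" = "SEVERELY",
  "a" = "ART", "an" = "ART", "the" = "ART")

.BIGRAMS <- list(
  c("AND", "IF", "AND_IF"),
  c("OR", "IF", "OR_IF"),
  c("WORD:at", "WORD:least", "AT_LEAST"),
  c("WORD:at", "WORD:most", "AT_MOST"),
  c("WORD:for", "WORD:each", "FOREACH"),
  c("WORD:defined", "WORD:as", "DEFINED_AS"),
  c("WORD:alpha", "WORD:to", "ALPHA_TO"))

tok <- function(type, value, raw, line, col)
  list(type = type, value = value, raw = raw, line = line, col = col)

logic_error <- function(msg, line = NA, col = NA) {
  loc <- if (!is.na(line)) sprintf(" (line %d, col %d)", line, col) else ""
  stop(structure(class = c("rf_logic_error", "error", "condition"),
                 list(message = paste0("logic error: ", msg, loc),
                      call = NULL)))
}

#' Tokenize logic source text
#'
#' Keywords are matched case-insensitively; multi-word operators
#' (\code{and if}, \code{or if}, \code{at least}, \code{at most},
#' \code{for each}, \code{defined as}, \code{alpha to}) are merged into
#' single tokens; number words \code{zero}..\code{ten} lex as integers;
#' \code{//} starts a comment running to end of line.  The token following
#' the \code{ghost} keyword is captured verbatim (it is a SMILES fragment).
#'
#' @param text Logic source (single string or character vector of lines).
#' @return List of tokens; each has \code{type}, \code{value}, \code{raw},
#'   \code{line}, \code{col}.
#' @export
tokenize <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  toks <- list()
  for (ln in seq_along(lines)) {
    s <- lines[ln]
    n <- nchar(s)
    i <- 1L
    ghost_next <- FALSE
    while (i <= n) {
      ch <- substr(s, i, i)
      if (grepl("^[ \t\r]$", ch)) { i <- i + 1L; next }
      if (ch == "/" && substr(s, i + 1L, i + 1L) == "/") break
      if (ghost_next) {
        rest <- substr(s, i, n)
        m <- regmatches(rest, regexpr("^\\S+", rest))
        toks[[length(toks) + 1L]] <- tok("STRING", m, m, ln, i)
        i <- i + nchar(m)
        ghost_next <- FALSE
        next
      }
      if (grepl("^[A-Za-z_]$", ch)) {
        rest <- substr(s, i, n)
        m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
        lw <- tolower(m)
        if (!is.na(NUMBER_WORDS[lw])) {
          toks[[length(toks) + 1L]] <- tok("INT", NUMBER_WORDS[[lw]], m, ln, i)
        } else if (!is.na(.KEYWORDS[lw])) {
          toks[[length(toks) + 1L]] <- tok(.KEYWORDS[[lw]], lw, m, ln, i)
          if (.KEYWORDS[[lw]] == "GHOST") ghost_next <- TRUE
        } else {
          toks[[length(toks) + 1L]] <- tok("WORD", lw, m, ln, i)
        }
        i <- i + nchar(m)
        next
      }
      if (grepl("^[0-9]$", ch)) {
        rest <- substr(s, i, n)
        m <- regmatches(rest, regexpr("^[0-9]+", rest))
        toks[[length(toks) + 1L]] <- tok("INT", as.integer(m), m, ln, i)
        i <- i + nchar(m)
        next
      }
      if (ch == "{") { toks[[length(toks) + 1L]] <- tok("LBRACE", "{", "{", ln, i); i <- i + 1L; next }
      if (ch == "}") { toks[[length(toks) + 1L]] <- tok("RBRACE", "}", "}", ln, i); i <- i + 1L; next }
      logic_error(paste0("illegal character '", ch, "'"), ln, i)
    }
  }
  ## merge multi-word operators (newlines are whitespace, so merge on the
  ## flattened stream)
  sig <- vapply(toks, function(t)
    if (t$type == "WORD") paste0("WORD:", t$value) else t$type, "")
  out <- list()
  i <- 1L
  while (i <= length(toks)) {
    merged <- FALSE
    if (i < length(toks)) {
      for (bg in .BIGRAMS) {
        if (sig[i] == bg[1] && sig[i + 1L] == bg[2]) {
          t1 <- toks[[i]]; t2 <- toks[[i + 1L]]
          out[[length(out) + 1L]] <- tok(bg[3], paste(t1$value, t2$value),
                                         paste(t1$raw, t2$raw),
                                         t1$line, t1$col)
          i <- i + 2L
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) {
      out[[length(out) + 1L]] <- toks[[i]]
      i <- i + 1L
    }
  }
  out
}

## ---- parser ---------------------------------------------------------------

new_parser <- function(toks) {
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$pos <- 1L
  env
}

p_peek <- function(p, k = 0L) {
  i <- p$pos + k
  if (i > length(p$toks)) NULL else p$toks[[i]]
}
p_type <- function(p, k = 0L) { t <- p_peek(p, k); if (is.null(t)) "EOF" else t$type }
p_next <- function(p) { t <- p_peek(p); p$pos <- p$pos + 1L; t }
p_expect <- function(p, type, what = type) {
  t <- p_peek(p)
  if (is.null(t))
    logic_error(paste0("unexpected end of input, expected ", what))
  if (t$type != type)
    logic_error(paste0("expected ", what, ", found '", t$raw, "'"),
                t$line, t$col)
  p_next(p)
}
p_accept <- function(p, type) {
  if (p_type(p) == type) p_next(p) else NULL
}
p_skip_articles <- function(p) while (p_type(p) == "ART") p_next(p)

## entity descriptors: a closed vocabulary describing a class of chemical
## objects ("carbon atom", "chlorines", "heteroatom", "hydrogen",
## "positive charge", "ring", "bond", "<name> group").
entity_node <- function(eclass, element = NULL, sign = NULL, group = NULL)
  list(kind = "entity", eclass = eclass, element = element, sign = sign,
       group = group)

p_parse_entity <- function(p, groups = NULL) {
  p_skip_articles(p)
  t <- p_peek(p)
  if (is.null(t)) logic_error("expected an entity descriptor, got end of input")
  depl <- function(w) sub("s$", "", w)            # crude plural strip
  if (t$type %in% c("ATOM", "ATOMS")) {
    p_next(p)
    return(entity_node("atom"))
  }
  if (t$type %in% c("BOND", "BONDS")) {
    p_next(p)
    return(entity_node("bond"))
  }
  if (t$type == "WORD") {
    w <- t$value
    ws <- depl(w)
    if (ws %in% names(ELEMENTS)) {
      p_next(p)
      if (p_type(p) %in% c("ATOM", "ATOMS")) p_next(p)
      return(entity_node("atom", element = ELEMENTS[[ws]]))
    }
    if (ws == "heteroatom") {
      p_next(p)
      return(entity_node("heteroatom"))
    }
    if (ws == "halogen") {
      p_next(p)
      if (p_type(p) %in% c("ATOM", "ATOMS")) p_next(p)
      return(entity_node("halogen"))
    }
    if (ws == "hydrogen") {
      p_next(p)
      return(entity_node("hydrogen"))
    }
    if (w %in% c("positive", "negative")) {
      sgn <- if (w == "positive") 1L else -1L
      p_next(p)
      nt <- p_peek(p)
      if (is.null(nt) || nt$type != "WORD" || depl(nt$value) != "charge")
        logic_error(paste0("expected 'charge' after '", w, "'"),
                    t$line, t$col)
      p_next(p)
      return(entity_node("charge", sign = sgn))
    }
    if (ws == "ring") {
      p_next(p)
      return(entity_node("ring"))
    }
    ## "<name> group(s)" -- the name itself is an open identifier checked
    ## against the group library at validation time
    nt <- p_peek(p, 1L)
    if (!is.null(nt) && nt$type == "WORD" && depl(nt$value) == "group") {
      p_next(p); p_next(p)
      return(entity_node("group", group = w))
    }
    logic_error(paste0("unknown entity descriptor '", t$raw, "'"),
                t$line, t$col)
  }
  logic_error(paste0("expected an entity descriptor, found '", t$raw, "'"),
              t$line, t$col)
}

p_parse_subject <- function(p) {
  t <- p_peek(p)
  if (is.null(t)) logic_error("expected a subject, got end of input")
  if (t$type == "ATOM") {
    p_next(p)
    n <- p_expect(p, "INT", "an atom map number")
    return(list(kind = "subject", stype = "ATOM",
                atom_refs = as.integer(n$value)))
  }
  if (t$type == "ALPHA_TO") {
    p_next(p)
    p_expect(p, "ATOM", "'atom'")
    n <- p_expect(p, "INT", "an atom map number")
    return(list(kind = "subject", stype = "ALPHA_TO_ATOM",
                atom_refs = as.integer(n$value)))
  }
  if (t$type == "BOND") {
    p_next(p)
    p_expect(p, "BETWEEN", "'between'")
    p_expect(p, "ATOM", "'atom'")
    n1 <- p_expect(p, "INT", "an atom map number")
    p_expect(p, "AND", "'and'")
    p_expect(p, "ATOM", "'atom'")
    n2 <- p_expect(p, "INT", "an atom map number")
    if (n1$value == n2$value)
      logic_error("bond subject needs two distinct atom map numbers",
                  t$line, t$col)
    return(list(kind = "subject", stype = "BOND",
                atom_refs = as.integer(c(n1$value, n2$value))))
  }
  if (t$type == "MOLECULE") {
    p_next(p)
    return(list(kind = "subject", stype = "MOLECULE", atom_refs = integer()))
  }
  if (t$type == "WORD") {
    p_next(p)
    return(list(kind = "subject", stype = "VARIABLE", atom_refs = integer(),
                var_name = t$value))
  }
  logic_error(paste0("expected a subject, found '", t$raw, "'"),
              t$line, t$col)
}

subject_start <- function(type) type %in% c("ATOM", "ALPHA_TO", "BOND",
                                            "MOLECULE", "WORD")

QUAL_SIMPLE <- c("aromatic", "aliphatic", "cyclic", "charged", "neutral")
CENTER_WORDS <- c("primary", "secondary", "tertiary", "quaternary")
BOND_ORDER_WORDS <- c("single", "double", "triple")

qual_pred <- function(name, entity = NULL, negated = FALSE)
  list(kind = "predicate", ptype = "QUALITATIVE", name = name,
       entity = entity, negated = negated)

p_parse_predicate_is <- function(p) {
  negated <- !is.null(p_accept(p, "NOT"))
  p_skip_articles(p)
  t <- p_peek(p)
  if (is.null(t)) logic_error("expected a predicate, got end of input")
  if (t$type == "WORD") {
    w <- t$value
    if (w %in% QUAL_SIMPLE) {
      p_next(p)
      return(qual_pred(w, negated = negated))
    }
    if (w %in% CENTER_WORDS) {
      p_next(p)
      ct <- p_peek(p)
      if (is.null(ct) || ct$type != "WORD" || ct$value != "center")
        logic_error(paste0("expected 'center' after '", w, "'"),
                    t$line, t$col)
      p_next(p)
      return(qual_pred(paste(w, "center"), negated = negated))
    }
    if (w %in% BOND_ORDER_WORDS) {
      p_next(p)
      if (p_type(p) %in% c("BOND", "BONDS")) p_next(p)
      return(qual_pred(paste(w, "bond"), negated = negated))
    }
    if (w == "origin") {
      p_next(p)
      p_expect(p, "OF", "'of'")
      g <- p_expect(p, "WORD", "a group name")
      gt <- p_peek(p)
      if (!is.null(gt) && gt$type == "WORD" &&
          gt$value %in% c("group", "groups")) p_next(p)
      return(list(kind = "predicate", ptype = "GROUP_ORIGIN",
                  name = g$value, negated = negated))
    }
  }
  if (t$type == "IN") {                      # "in a ring"
    p_next(p)
    p_skip_articles(p)
    rt <- p_peek(p)
    if (is.null(rt) || rt$type != "WORD" || sub("s$", "", rt$value) != "ring")
      logic_error("expected 'ring' after 'in'",
                  t$line, t$col)
    p_next(p)
    return(qual_pred("cyclic", negated = negated))
  }
  ## fall through: an entity descriptor used as a class test
  ## ("is carbon atom", "is a heteroatom")
  ent <- p_parse_entity(p)
  qual_pred("entity", entity = ent, negated = negated)
}

p_parse_predicate_has <- function(p) {
  negated <- !is.null(p_accept(p, "NOT"))
  quantifier <- "EXACTLY"
  t <- p_peek(p)
  if (!is.null(t)) {
    if (t$type == "AT_LEAST") { p_next(p); quantifier <- "AT_LEAST" }
    else if (t$type == "AT_MOST") { p_next(p); quantifier <- "AT_MOST" }
    else if (t$type == "EXACTLY") { p_next(p) }
  }
  n <- p_expect(p, "INT", "a count")
  ent <- p_parse_entity(p)
  ## optional trailing "attached to it"
  at <- p_peek(p)
  if (!is.null(at) && at$type == "WORD" && at$value == "attached") {
    p_next(p)
    tt <- p_peek(p)
    if (!is.null(tt) && tt$type == "WORD" && tt$value == "to") {
      p_next(p)
      it <- p_peek(p)
      if (!is.null(it) && it$type == "WORD" && it$value == "it") p_next(p)
    }
  }
  list(kind = "predicate", ptype = "QUANTITATIVE",
       quantifier = quantifier, count = as.integer(n$value),
       counted = ent, negated = negated)
}

p_parse_where <- function(p) {
  if (!is.null(p_accept(p, "OFFPATH"))) return("OFFPATH")
  if (!is.null(p_accept(p, "ONPATH"))) return("ONPATH")
  "NONE"
}

p_parse_condition <- function(p) {
  subjects <- list(p_parse_subject(p))
  subj_comb <- NA_character_
  while (p_type(p) %in% c("AND", "OR") && subject_start(p_type(p, 1L)) &&
         !(p_type(p, 1L) == "WORD" &&
           !p_type(p, 2L) %in% c("IS", "HAS", "AND", "OR"))) {
    op <- p_next(p)$type
    if (!is.na(subj_comb) && subj_comb != op)
      logic_error("mixed 'and'/'or' between subjects of one condition")
    subj_comb <- op
    subjects[[length(subjects) + 1L]] <- p_parse_subject(p)
  }
  rel_tok <- p_peek(p)
  relation <-
    if (p_type(p) == "IS") { p_next(p); "IS" }
    else if (p_type(p) == "HAS") { p_next(p); "HAS" }
    else logic_error(paste0("expected 'is'/'are' or 'has'/'have'",
                            if (!is.null(rel_tok))
                              paste0(", found '", rel_tok$raw, "'") else ""),
                     if (is.null(rel_tok)) NA else rel_tok$line,
                     if (is.null(rel_tok)) NA else rel_tok$col)
  parse_pred <- if (relation == "IS") p_parse_predicate_is else p_parse_predicate_has
  predicates <- list(parse_pred(p))
  pred_comb <- NA_character_
  while (p_type(p) %in% c("AND", "OR")) {
    op <- p_next(p)$type
    if (!is.na(pred_comb) && pred_comb != op)
      logic_error("mixed 'and'/'or' between predicates of one condition")
    pred_comb <- op
    predicates[[length(predicates) + 1L]] <- parse_pred(p)
  }
  where <- p_parse_where(p)
  list(kind = "condition", subjects = subjects, subj_comb = subj_comb,
       relation = relation, predicates = predicates, pred_comb = pred_comb,
       where = where)
}

p_parse_action <- function(p) {
  t <- p_peek(p)
  if (is.null(t)) logic_error("expected an action after 'then'")
  if (t$type == "KILL") {
    p_next(p)
    return(list(kind = "action", atype = "KILL"))
  }
  if (t$type %in% c("RAISE", "LOWER")) {
    p_next(p)
    p_expect(p, "RATING", "'rating'")
    mt <- p_peek(p)
    if (is.null(mt) || !mt$type %in% c("SLIGHTLY", "MODERATELY",
                                       "STRONGLY", "SEVERELY"))
      logic_error("expected a magnitude (slightly/moderately/strongly/severely)",
                  t$line, t$col)
    p_next(p)
    return(list(kind = "action", atype = "ADJUST_RATING",
                direction = if (t$type == "RAISE") "RAISE" else "LOWER",
                magnitude = mt$type))
  }
  if (t$type == "GHOST") {
    p_next(p)
    st <- p_peek(p)
    if (is.null(st) || st$type != "STRING")
      logic_error("expected a SMILES fragment after 'ghost'",
                  t$line, t$col)
    p_next(p)
    return(list(kind = "action", atype = "GHOST", ghost_fragment = st$value))
  }
  logic_error(paste0("expected an action, found '", t$raw, "'"),
              t$line, t$col)
}

p_parse_statement <- function(p) {
  p_expect(p, "IF", "'if'")
  clauses <- list(list(comb = "FIRST", condition = p_parse_condition(p)))
  while (p_type(p) %in% c("AND_IF", "OR_IF")) {
    op <- p_next(p)$type
    clauses[[length(clauses) + 1L]] <-
      list(comb = op, condition = p_parse_condition(p))
  }
  p_expect(p, "THEN", "'then'")
  action <- p_parse_action(p)
  list(kind = "statement", clauses = clauses, action = action)
}

p_parse_loop <- function(p) {
  ft <- p_expect(p, "FOREACH", "'foreach'")
  iterand <- p_parse_entity(p)
  where <- p_parse_where(p)
  p_expect(p, "DEFINED_AS", "'defined as'")
  v <- p_expect(p, "WORD", "a variable name")
  p_expect(p, "IN", "'in'")
  ct <- p_peek(p)
  container <-
    if (p_type(p) == "MOLECULE") { p_next(p); list(ctype = "MOLECULE") }
    else if (p_type(p) == "WORD" && ct$value == "rings") {
      p_next(p); list(ctype = "RINGS")
    } else if (p_type(p) == "WORD") {
      p_next(p); list(ctype = "NAMED_SET", name = ct$value)
    } else logic_error("expected 'molecule', 'rings' or a set name after 'in'",
                       ft$line, ft$col)
  p_expect(p, "LBRACE", "'{' opening the loop body")
  body <- p_parse_program_items(p, stop_at_rbrace = TRUE)
  p_expect(p, "RBRACE", "'}' closing the loop body")
  list(kind = "loop", iterand = iterand, where = where, var_name = v$value,
       container = container,
       body = structure(list(kind = "program", items = body),
                        class = "rf_program"))
}

p_parse_setdef <- function(p) {
  p_next(p)                                   # 'define'
  st <- p_peek(p)
  if (is.null(st) || st$type != "WORD" || st$value != "set")
    logic_error("expected 'set' after 'define'")
  p_next(p)
  nm <- p_expect(p, "WORD", "a set name")
  as_t <- p_peek(p)
  if (is.null(as_t) || as_t$type != "WORD" || as_t$value != "as")
    logic_error("expected 'as' in set definition", nm$line, nm$col)
  p_next(p)
  ent <- p_parse_entity(p)
  where <- p_parse_where(p)
  list(kind = "setdef", name = nm$value, entity = ent, where = where)
}

p_parse_program_items <- function(p, stop_at_rbrace = FALSE) {
  items <- list()
  repeat {
    t <- p_type(p)
    if (t == "EOF") break
    if (t == "RBRACE" && stop_at_rbrace) break
    if (t == "IF") items[[length(items) + 1L]] <- p_parse_statement(p)
    else if (t == "FOREACH") items[[length(items) + 1L]] <- p_parse_loop(p)
    else if (t == "WORD" && p_peek(p)$value == "define")
      items[[length(items) + 1L]] <- p_parse_setdef(p)
    else {
      tk <- p_peek(p)
      logic_error(paste0("expected 'if', 'foreach' or 'define', found '",
                         tk$raw, "'"), tk$line, tk$col)
    }
  }
  items
}

check_variable_scopes <- function(items, in_scope = character()) {
  for (it in items) {
    if (it$kind == "setdef") {
      in_scope <- c(in_scope, it$name)
    } else if (it$kind == "loop") {
      if (it$var_name %in% in_scope)
        logic_error(paste0("loop variable '", it$var_name,
                           "' shadows an enclosing name"))
      if (it$container$ctype == "NAMED_SET" &&
          !(it$container$name %in% in_scope))
        logic_error(paste0("loop iterates over undefined set '",
                           it$container$name, "'"))
      check_variable_scopes(it$body$items, c(in_scope, it$var_name))
    } else if (it$kind == "statement") {
      for (cl in it$clauses) {
        for (s in cl$condition$subjects) {
          if (s$stype == "VARIABLE" && !(s$var_name %in% in_scope))
            logic_error(paste0("unresolved variable '", s$var_name, "'"))
        }
      }
    }
  }
  invisible(in_scope)
}

#' Parse a logic program
#'
#' @param text Logic source text.
#' @return A program AST (\code{rf_program}): a list of statements, loops
#'   and set definitions, validated for variable scoping.
#' @examples
#' \dontrun{
#' parse_program("if atom 1 is carbon atom and if atom 1 is aromatic then kill")
#' }
#' @export
parse_program <- function(text) {
  p <- new_parser(tokenize(text))
  items <- p_parse_program_items(p)
  if (p_type(p) != "EOF") {
    t <- p_peek(p)
    logic_error(paste0("unexpected '", t$raw, "' after program end"),
                t$line, t$col)
  }
  check_variable_scopes(items)
  structure(list(kind = "program", items = items), class = "rf_program")
}

## ---- canonical serializer -------------------------------------------------

ELEMENT_NAMES <- structure(names(ELEMENTS)[!duplicated(ELEMENTS)],
                           names = ELEMENTS[!duplicated(ELEMENTS)])

ser_entity <- function(e, plural = FALSE) {
  s <- function(base) if (plural) paste0(base, "s") else base
  switch(e$eclass,
    atom = if (is.null(e$element)) s("atom")
           else paste(ELEMENT_NAMES[[e$element]], s("atom")),
    heteroatom = s("heteroatom"),
    halogen = s("halogen"),
    hydrogen = s("hydrogen"),
    charge = paste(if (e$sign > 0) "positive" else "negative", s("charge")),
    ring = s("ring"),
    bond = s("bond"),
    group = paste(e$group, s("group")),
    stop("unknown entity class: ", e$eclass))
}

ser_subject <- function(s) {
  switch(s$stype,
    ATOM = paste("atom", s$atom_refs[1]),
    ALPHA_TO_ATOM = paste("alpha to atom", s$atom_refs[1]),
    BOND = paste("bond between atom", s$atom_refs[1], "and atom",
                 s$atom_refs[2]),
    MOLECULE = "molecule",
    VARIABLE = s$var_name)
}

ser_predicate <- function(pr) {
  neg <- if (isTRUE(pr$negated)) "not " else ""
  if (pr$ptype == "QUALITATIVE") {
    body <- if (pr$name == "entity") ser_entity(pr$entity) else pr$name
    return(paste0(neg, body))
  }
  if (pr$ptype == "GROUP_ORIGIN")
    return(paste0(neg, "the origin of ", pr$name, " group"))
  q <- switch(pr$quantifier, AT_LEAST = "at least ", AT_MOST = "at most ",
              EXACTLY = "exactly ")
  paste0(neg, q, pr$count, " ", ser_entity(pr$counted, plural = pr$count != 1L))
}

ser_condition <- function(c) {
  sc <- if (is.na(c$subj_comb)) "" else tolower(c$subj_comb)
  subj <- paste(vapply(c$subjects, ser_subject, ""),
                collapse = paste0(" ", sc, " "))
  rel <- if (c$relation == "IS") "is" else "has"
  pc <- if (is.na(c$pred_comb)) "" else tolower(c$pred_comb)
  preds <- paste(vapply(c$predicates, ser_predicate, ""),
                 collapse = paste0(" ", pc, " "))
  out <- paste(subj, rel, preds)
  if (c$where != "NONE") out <- paste(out, tolower(c$where))
  out
}

ser_action <- function(a) {
  switch(a$atype,
    KILL = "kill",
    ADJUST_RATING = paste(tolower(a$direction), "rating",
                          tolower(a$magnitude)),
    GHOST = paste("ghost", a$ghost_fragment))
}

ser_statement <- function(st) {
  parts <- character()
  for (cl in st$clauses) {
    kw <- switch(cl$comb, FIRST = "if", AND_IF = "and if", OR_IF = "or if")
    parts <- c(parts, paste(kw, ser_condition(cl$condition)))
  }
  paste(paste(parts, collapse = " "), "then", ser_action(st$action))
}

ser_item <- function(it, indent = "") {
  if (it$kind == "statement")
    return(paste0(indent, ser_statement(it)))
  if (it$kind == "setdef") {
    out <- paste0(indent, "define set ", it$name, " as ",
                  ser_entity(it$entity, plural = TRUE))
    if (it$where != "NONE") out <- paste(out, tolower(it$where))
    return(out)
  }
  ## loop
  head <- paste0(indent, "foreach ", ser_entity(it$iterand))
  if (it$where != "NONE") head <- paste(head, tolower(it$where))
  head <- paste0(head, " defined as ", it$var_name, " in ",
                 switch(it$container$ctype, MOLECULE = "molecule",
                        RINGS = "rings", NAMED_SET = it$container$name),
                 " {")
  body <- vapply(it$body$items, ser_item, "", indent = paste0(indent, "  "))
  paste(c(head, body, paste0(indent, "}")), collapse = "\n")
}

#' Serialize a logic program to canonical source text
#'
#' Canonical form: lower-case keywords, one statement per line, loops as
#' brace-delimited blocks with two-space indentation.  Reparsing the output
#' reproduces the AST exactly.
#'
#' @param p An \code{rf_program}.
#' @return A single string (empty string for an empty program).
#' @export
serialize_program <- function(p) {
  stopifnot(inherits(p, "rf_program") || identical(p$kind, "program"))
  if (!length(p$items)) return("")
  paste(vapply(p$items, ser_item, ""), collapse = "\n")
}

#' @export
print.rf_program <- function(x, ...) {
  cat("<rf_program> ", length(x$items), " top-level item(s)\n", sep = "")
  src <- serialize_program(x)
  if (nzchar(src)) cat(src, "\n", sep = "")
  invisible(x)
}

## atom map numbers referenced anywhere in a program (for transform
## validation)
program_atom_refs <- function(p) {
  refs <- integer()
  walk <- function(items) {
    for (it in items) {
      if (it$kind == "statement") {
        for (cl in it$clauses)
          for (s in cl$condition$subjects)
            refs <<- c(refs, s$atom_refs)
      } else if (it$kind == "loop") walk(it$body$items)
    }
  }
  walk(p$items)
  sort(unique(refs))
}

## group names referenced anywhere in a program
program_group_refs <- function(p) {
  out <- character()
  walk <- function(items) {
    for (it in items) {
      if (it$kind == "statement") {
        for (cl in it$clauses)
          for (pr in cl$condition$predicates) {
            if (pr$ptype == "GROUP_ORIGIN") out <<- c(out, pr$name)
            if (pr$ptype == "QUANTITATIVE" && pr$counted$eclass == "group")
              out <<- c(out, pr$counted$group)
            if (pr$ptype == "QUALITATIVE" && !is.null(pr$entity) &&
                pr$entity$eclass == "group")
              out <<- c(out, pr$entity$group)
          }
      } else if (it$kind == "loop") {
        if (it$iterand$eclass == "group") out <<- c(out, it$iterand$group)
        walk(it$body$items)
      } else if (it$kind == "setdef" && it$entity$eclass == "group")
        out <<- c(out, it$entity$group)
    }
  }
  walk(p$items)
  sort(unique(out))
}
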