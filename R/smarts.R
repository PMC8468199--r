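# ---------------------------------------------------------------------------
# A compact substructure matcher for a documented subset of SMARTS, sufficient
# for the default feature-perception rules and user rule files.
#
# Supported syntax:
#   atoms      C N O S P B F I Cl Br (aliphatic), c n o s p b (aromatic), *
#   brackets   [ ... ] with primitives:
#                #<n>   atomic number        H<n>   total H count (H = >=1)
#                X<n>   connectivity         + / -  formal charge sign
#                A / a  aliphatic / aromatic * any
#                element symbols (case gives aromaticity)
#                $(<smarts>)  recursive environment rooted at the atom
#              logic: ! (not) > & or juxtaposition (and) > , (or) > ; (and)
#   bonds      - = # : ~  (default bond: single-or-aromatic)
#   branches   ( ... ) ; ring closures: single digits 1-9
#
# Not supported (rejected at parse time): charge multiplicity (++), @/@@
# chirality, D/R/r/v primitives, two-digit %nn ring closures, '.' components.
# ---------------------------------------------------------------------------

ATOMIC_NUMBER <- c(H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L,
                   Na = 11L, Mg = 12L, Si = 14L, P = 15L, S = 16L,
                   Cl = 17L, K = 19L, Ca = 20L, Se = 34L, Br = 35L, I = 53L)

#' Parse a SMARTS pattern (supported subset)
#'
#' @param s pattern string.
#' @return an object of class `smarts_pattern` (atom expression trees plus a
#'   bond list), usable with [smarts_match()].
#' @export
parse_smarts <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  st <- new.env(parent = emptyenv())
  st$s <- s; st$pos <- 1L; st$n <- nchar(s)
  st$atoms <- list(); st$bonds <- list(); st$ring_open <- list()
  parse_sm_chain(st, prev = NA_integer_)
  if (st$pos <= st$n)
    stop(sprintf("SMARTS parse error in '%s' at position %d", s, st$pos))
  if (length(st$ring_open))
    stop(sprintf("unclosed ring bond in SMARTS '%s'", s))
  structure(list(src = s, atoms = st$atoms,
                 bonds = do.call(rbind, st$bonds) %||%
                   matrix(integer(), 0, 2),
                 bond_sym = vapply(st$bonds, attr, "", which = "sym")),
            class = "smarts_pattern")
}

sm_peek <- function(st) if (st$pos > st$n) "" else substr(st$s, st$pos, st$pos)
sm_take <- function(st) { ch <- sm_peek(st); st$pos <- st$pos + 1L; ch }

parse_sm_chain <- function(st, prev) {
  repeat {
    ch <- sm_peek(st)
    if (ch == "" || ch == ")") return(invisible())
    if (ch == "(") {
      if (is.na(prev)) stop("branch cannot start a SMARTS")
      sm_take(st)
      parse_sm_chain(st, prev)
      if (sm_take(st) != ")") stop("unbalanced parenthesis in SMARTS")
      next
    }
    bond <- ""
    if (ch %in% c("-", "=", "#", ":", "~")) { bond <- sm_take(st); ch <- sm_peek(st) }
    if (grepl("^[1-9]$", ch)) {           # ring closure
      sm_take(st)
      if (is.na(prev)) stop("ring closure before any atom")
      key <- ch
      if (!is.null(st$ring_open[[key]])) {
        op <- st$ring_open[[key]]
        st$ring_open[[key]] <- NULL
        sym <- if (nzchar(bond)) bond else op$sym
        st$bonds[[length(st$bonds) + 1L]] <-
          structure(matrix(c(op$atom, prev), 1), sym = sym %||% "")
      } else st$ring_open[[key]] <- list(atom = prev, sym = bond)
      next
    }
    idx <- parse_sm_atom(st)
    if (!is.na(prev))
      st$bonds[[length(st$bonds) + 1L]] <-
        structure(matrix(c(prev, idx), 1), sym = bond)
    prev <- idx
  }
}

parse_sm_atom <- function(st) {
  ch <- sm_peek(st)
  expr <- if (ch == "[") {
    sm_take(st)
    e <- parse_sm_expr(st)
    if (sm_take(st) != "]") stop("expected ] in SMARTS")
    e
  } else {
    two <- substr(st$s, st$pos, st$pos + 1L)
    if (two %in% c("Cl", "Br")) {
      st$pos <- st$pos + 2L
      list(op = "prim", kind = "elem_ali", value = two)
    } else if (ch %in% c("B", "C", "N", "O", "S", "P", "F", "I")) {
      sm_take(st); list(op = "prim", kind = "elem_ali", value = ch)
    } else if (ch %in% c("b", "c", "n", "o", "s", "p")) {
      sm_take(st); list(op = "prim", kind = "elem_aro", value = toupper(ch))
    } else if (ch == "*") {
      sm_take(st); list(op = "prim", kind = "any")
    } else stop(sprintf("unexpected character '%s' in SMARTS at %d", ch, st$pos))
  }
  st$atoms[[length(st$atoms) + 1L]] <- expr
  length(st$atoms)
}

# precedence: ';' < ',' < '&'/juxtaposition < '!'
parse_sm_expr <- function(st) {
  parts <- list(parse_sm_or(st))
  while (sm_peek(st) == ";") { sm_take(st); parts <- c(parts, list(parse_sm_or(st))) }
  if (length(parts) == 1L) parts[[1]] else list(op = "and", args = parts)
}
parse_sm_or <- function(st) {
  parts <- list(parse_sm_and(st))
  while (sm_peek(st) == ",") { sm_take(st); parts <- c(parts, list(parse_sm_and(st))) }
  if (length(parts) == 1L) parts[[1]] else list(op = "or", args = parts)
}
parse_sm_and <- function(st) {
  parts <- list(parse_sm_factor(st))
  repeat {
    ch <- sm_peek(st)
    if (ch == "&") { sm_take(st); parts <- c(parts, list(parse_sm_factor(st))); next }
    if (ch %in% c("", "]", ";", ",", ")")) break
    parts <- c(parts, list(parse_sm_factor(st)))   # juxtaposition
  }
  if (length(parts) == 1L) parts[[1]] else list(op = "and", args = parts)
}
parse_sm_factor <- function(st) {
  ch <- sm_peek(st)
  if (ch == "!") { sm_take(st); return(list(op = "not", arg = parse_sm_factor(st))) }
  if (ch == "#") {
    sm_take(st)
    num <- sm_digits(st)
    if (is.na(num)) stop("expected atomic number after #")
    return(list(op = "prim", kind = "elem_z", value = num))
  }
  if (ch == "$") {
    sm_take(st)
    if (sm_take(st) != "(") stop("expected ( after $ in SMARTS")
    depth <- 1L; start <- st$pos
    while (depth > 0L) {
      c2 <- sm_take(st)
      if (c2 == "") stop("unbalanced $() in SMARTS")
      if (c2 == "(") depth <- depth + 1L
      if (c2 == ")") depth <- depth - 1L
    }
    sub <- substr(st$s, start, st$pos - 2L)
    return(list(op = "prim", kind = "recursive", value = parse_smarts(sub)))
  }
  if (ch == "H") { sm_take(st); return(list(op = "prim", kind = "hcount", value = sm_digits(st))) }
  if (ch == "X") {
    sm_take(st); num <- sm_digits(st)
    if (is.na(num)) stop("expected number after X")
    return(list(op = "prim", kind = "conn", value = num))
  }
  if (ch == "+") { sm_take(st); return(list(op = "prim", kind = "charge", value = 1L)) }
  if (ch == "-") { sm_take(st); return(list(op = "prim", kind = "charge", value = -1L)) }
  if (ch == "*") { sm_take(st); return(list(op = "prim", kind = "any")) }
  if (ch == "a") { sm_take(st); return(list(op = "prim", kind = "arom", value = TRUE)) }
  if (ch == "A") { sm_take(st); return(list(op = "prim", kind = "arom", value = FALSE)) }
  two <- substr(st$s, st$pos, st$pos + 1L)
  if (two %in% c("Cl", "Br", "Na", "Mg", "Si", "Se", "Ca")) {
    st$pos <- st$pos + 2L
    return(list(op = "prim", kind = "elem_ali", value = two))
  }
  if (grepl("^[B-Z]$", ch)) { sm_take(st); return(list(op = "prim", kind = "elem_ali", value = ch)) }
  if (ch %in% c("b", "c", "n", "o", "s", "p")) {
    sm_take(st); return(list(op = "prim", kind = "elem_aro", value = toupper(ch)))
  }
  stop(sprintf("unexpected character '%s' in SMARTS atom expression", ch))
}
sm_digits <- function(st) {
  out <- ""
  while (grepl("^[0-9]$", sm_peek(st))) out <- paste0(out, sm_take(st))
  if (nzchar(out)) as.integer(out) else NA_integer_
}

sm_eval_atom <- function(expr, mol, i) {
  switch(expr$op,
    and = all(vapply(expr$args, sm_eval_atom, logical(1), mol = mol, i = i)),
    or  = any(vapply(expr$args, sm_eval_atom, logical(1), mol = mol, i = i)),
    not = !sm_eval_atom(expr$arg, mol, i),
    prim = {
      a <- mol$atoms
      switch(expr$kind,
        any      = TRUE,
        elem_ali = a$elem[i] == expr$value && !a$aromatic[i],
        elem_aro = a$elem[i] == expr$value && a$aromatic[i],
        elem_z   = identical(unname(ATOMIC_NUMBER[a$elem[i]]), expr$value),
        arom     = a$aromatic[i] == expr$value,
        hcount   = if (is.na(expr$value)) mol$graph$nH[i] >= 1L
                   else mol$graph$nH[i] == expr$value,
        conn     = mol$graph$degree[i] == expr$value,
        charge   = if (expr$value > 0) a$charge[i] > 0 else a$charge[i] < 0,
        recursive = nrow(smarts_match(mol, expr$value, root = i,
                                      first_only = TRUE)) > 0L,
        stop("unknown primitive"))
    },
    stop("unknown expression node"))
}

sm_eval_bond <- function(sym, mol, i, j, order) {
  ar <- bond_is_aromatic(mol, i, j)
  switch(sym,
    "-" = order == 1L && !ar,
    "=" = order == 2L,
    "#" = order == 3L,
    ":" = ar,
    "~" = TRUE,
    (order == 1L && !ar) || ar)   # default single-or-aromatic
}

#' Match a parsed SMARTS pattern against a molecule
#'
#' Backtracking subgraph search. Matches are returned as a matrix with one
#' row per embedding and one column per pattern atom (molecule atom indices).
#'
#' @param mol a `molecule3d`.
#' @param pattern a `smarts_pattern` from [parse_smarts()] (or a string).
#' @param root optionally constrain pattern atom 1 to this molecule atom.
#' @param first_only stop at the first embedding (used by recursive SMARTS).
#' @param unique_sets drop embeddings that reuse the same atom set.
#' @return integer matrix of embeddings (possibly 0 rows).
#' @export
smarts_match <- function(mol, pattern, root = NULL, first_only = FALSE,
                         unique_sets = TRUE) {
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  np <- length(pattern$atoms)
  nb <- nrow(pattern$bonds)
  # adjacency of the pattern graph
  padj <- vector("list", np)
  if (nb) for (k in seq_len(nb)) {
    a <- pattern$bonds[k, 1]; b <- pattern$bonds[k, 2]
    padj[[a]] <- rbind(padj[[a]], c(b, k))
    padj[[b]] <- rbind(padj[[b]], c(a, k))
  }
  n <- n_atoms(mol)
  results <- list()
  assign_vec <- rep(NA_integer_, np)
  used <- rep(FALSE, n)

  bond_tbl <- if (nrow(mol$bonds))
    stats::setNames(mol$bonds$order, paste(mol$bonds$i, mol$bonds$j)) else
    stats::setNames(integer(0), character(0))
  mol_order <- function(i, j) {
    o <- bond_tbl[[paste(min(i, j), max(i, j))]]
    if (is.null(o)) NA_integer_ else o
  }

  ok_pair <- function(p, q, mi, mj) {
    # all pattern bonds between assigned atoms must be realized
    TRUE
  }

  check_edges <- function(p, cand) {
    if (is.null(padj[[p]])) return(TRUE)
    for (r in seq_len(nrow(padj[[p]]))) {
      q <- padj[[p]][r, 1]; k <- padj[[p]][r, 2]
      mq <- assign_vec[q]
      if (is.na(mq)) next
      o <- mol_order(cand, mq)
      if (is.na(o)) return(FALSE)
      if (!sm_eval_bond(pattern$bond_sym[k], mol, cand, mq, o)) return(FALSE)
    }
    TRUE
  }

  rec <- function(p) {
    if (first_only && length(results)) return(invisible())
    if (p > np) { results[[length(results) + 1L]] <<- assign_vec; return(invisible()) }
    cands <- if (p == 1L) {
      if (!is.null(root)) root else seq_len(n)
    } else {
      # candidates restricted to neighbours of an already-assigned pattern atom
      anchor <- NULL
      if (!is.null(padj[[p]])) for (r in seq_len(nrow(padj[[p]]))) {
        q <- padj[[p]][r, 1]
        if (!is.na(assign_vec[q])) { anchor <- assign_vec[q]; break }
      }
      if (is.null(anchor)) seq_len(n) else mol$graph$adj[[anchor]] %||% integer()
    }
    for (cand in cands) {
      if (used[cand]) next
      if (!sm_eval_atom(pattern$atoms[[p]], mol, cand)) next
      if (!check_edges(p, cand)) next
      assign_vec[p] <<- cand; used[cand] <<- TRUE
      rec(p + 1L)
      assign_vec[p] <<- NA_integer_; used[cand] <<- FALSE
      if (first_only && length(results)) return(invisible())
    }
    invisible()
  }
  rec(1L)
  if (!length(results))
    return(matrix(integer(), 0, np))
  m <- do.call(rbind, results)
  if (unique_sets && nrow(m) > 1L) {
    key <- apply(m, 1, function(r) paste(sort(r), collapse = "-"))
    m <- m[!duplicated(key), , drop = FALSE]
  }
  m
}
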