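# SMILES -> molecular graph construction.
#
# Molecules are represented as labeled undirected simple graphs G = (V, E):
# one node per atom, one edge per bond irrespective of bond order or
# aromaticity.  Bond orders are recorded only to count implicit hydrogens.

.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)
.ORGANIC_SUBSET <- names(.DEFAULT_VALENCE)
.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")

#' Molecular graph constructor (internal)
#'
#' @param element character vector of element symbols, one per node
#' @param aromatic logical vector, aromatic flag per node
#' @param origin "parsed" or "added-hydrogen" per node
#' @param edges integer matrix with two columns (i < j), one row per edge
#' @param bond_order numeric vector, nominal order per edge (1, 2, 3;
#'   aromatic ring bonds are stored as 1 and flagged through the atoms)
#' @param implicit_h integer vector of implicit hydrogen counts per node
#'   (0 for added hydrogens)
#' @param name,smiles optional molecule name and source SMILES
#' @noRd
new_molgraph <- function(element, aromatic, origin, edges, bond_order,
                         implicit_h, name = NULL, smiles = NULL) {
  structure(list(element = element, aromatic = aromatic, origin = origin,
                 edges = edges, bond_order = bond_order,
                 implicit_h = implicit_h, name = name, smiles = smiles),
            class = "molgraph")
}

#' Number of atoms / bonds in a molecular graph
#'
#' @param g a \code{molgraph}
#' @return integer count of nodes (\code{n_atoms}) or edges (\code{n_bonds}).
#' @export
n_atoms <- function(g) length(g$element)

#' @rdname n_atoms
#' @export
n_bonds <- function(g) nrow(g$edges)

#' @export
print.molgraph <- function(x, ...) {
  hs <- sum(x$origin == "added-hydrogen")
  cat(sprintf("Molecular graph%s: %d atoms, %d bonds%s\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
              n_atoms(x), n_bonds(x),
              if (hs > 0) sprintf(" (%d explicit H)", hs) else
                " (hydrogen-suppressed)"))
  tab <- table(x$element)
  cat("  composition:",
      paste(sprintf("%s%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  invisible(x)
}

#' Parse a SMILES string into a hydrogen-suppressed molecular graph
#'
#' Supports the organic subset (B, C, N, O, P, S, F, Cl, Br, I), bracket
#' atoms with explicit hydrogen counts and charges, ring-closure digits
#' (including \code{\%nn}), branches, bond symbols and aromatic lowercase
#' forms.  Heavy atoms are numbered in SMILES token order, which makes
#' adjacency matrices reproducible bit-for-bit.
#'
#' Bond orders and aromaticity are recorded only for hydrogen counting;
#' every bond contributes exactly one edge.
#'
#' @param text a single SMILES string (one fragment)
#' @param name optional molecule name carried through to outputs
#' @return a \code{molgraph} with implicit hydrogen counts per heavy atom.
#' @examples
#' g <- parse_smiles("CCCO")
#' n_atoms(g)  # 4 heavy atoms
#' @export
parse_smiles <- function(text, name = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single SMILES string", call. = FALSE)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  nc <- length(chars)
  if (nc == 0L) stop("empty SMILES string", call. = FALSE)
  perr <- function(pos, msg)
    stop(sprintf("SMILES parse error at position %d ('%s'): %s",
                 pos, text, msg), call. = FALSE)

  element <- character(0); aromatic <- logical(0)
  bracket <- logical(0); bracket_h <- integer(0); charge <- integer(0)
  e_i <- integer(0); e_j <- integer(0); e_ord <- numeric(0)
  add_edge <- function(a, b, ord) {
    if (a == b) perr(i, "self-bond")
    lo <- min(a, b); hi <- max(a, b)
    dup <- any(e_i == lo & e_j == hi)
    if (dup) perr(i, "duplicate bond between atoms")
    e_i <<- c(e_i, lo); e_j <<- c(e_j, hi); e_ord <<- c(e_ord, ord)
  }

  prev <- 0L                 # last atom emitted (0 = none yet)
  stack <- integer(0)        # branch stack
  pending <- NA_real_        # bond order awaiting the next atom/ring bond
  ring_atom <- list()        # ring-closure label -> opening atom
  ring_ord <- list()         # ring-closure label -> bond order (NA = default)
  i <- 1L

  emit_atom <- function(el, arom, brk, hc, chg) {
    element <<- c(element, el); aromatic <<- c(aromatic, arom)
    bracket <<- c(bracket, brk); bracket_h <<- c(bracket_h, hc)
    charge <<- c(charge, chg)
    idx <- length(element)
    if (prev > 0L) {
      ord <- pending
      if (is.na(ord)) ord <- if (arom && aromatic[prev]) 1 else 1
      add_edge(prev, idx, ord)
    } else if (!is.na(pending)) {
      perr(i, "bond symbol with no preceding atom")
    }
    pending <<- NA_real_
    prev <<- idx
    invisible(idx)
  }

  close_ring <- function(key) {
    if (prev == 0L) perr(i, "ring closure before any atom")
    if (is.null(ring_atom[[key]])) {
      ring_atom[[key]] <<- prev
      ring_ord[[key]] <<- pending
      pending <<- NA_real_
    } else {
      other <- ring_atom[[key]]
      stored <- ring_ord[[key]]
      ord <- pending
      if (is.na(ord)) ord <- stored
      if (!is.na(stored) && !is.na(pending) && stored != pending)
        perr(i, sprintf("conflicting bond orders for ring closure %s", key))
      if (is.na(ord)) ord <- 1
      add_edge(other, prev, ord)
      ring_atom[[key]] <<- NULL; ring_ord[[key]] <<- NULL
      pending <<- NA_real_
    }
  }

  while (i <= nc) {
    ch <- chars[i]
    if (ch == ".") perr(i, "multi-fragment SMILES (dot) is unsupported")
    if (ch %in% c("-", "/", "\\")) { pending <- 1; i <- i + 1L; next }
    if (ch == "=") { pending <- 2; i <- i + 1L; next }
    if (ch == "#") { pending <- 3; i <- i + 1L; next }
    if (ch == ":") { pending <- 1; i <- i + 1L; next }
    if (ch == "(") {
      if (prev == 0L) perr(i, "branch with no preceding atom")
      stack <- c(stack, prev); i <- i + 1L; next
    }
    if (ch == ")") {
      if (length(stack) == 0L) perr(i, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (grepl("^[0-9]$", ch)) { close_ring(ch); i <- i + 1L; next }
    if (ch == "%") {
      if (i + 2L > nc || !grepl("^[0-9][0-9]$",
                                paste0(chars[i + 1L], chars[i + 2L])))
        perr(i, "'%' must be followed by two digits")
      close_ring(paste0("%", chars[i + 1L], chars[i + 2L]))
      i <- i + 3L; next
    }
    if (ch == "[") {
      j <- i + 1L
      close_pos <- NA_integer_
      for (k in j:nc) if (chars[k] == "]") { close_pos <- k; break }
      if (is.na(close_pos)) perr(i, "unclosed bracket atom")
      body <- paste(chars[j:(close_pos - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Z][a-z]?|[bcnops])(@{0,2})(H([0-9]*))?([+-][0-9]*|\\+*|-*)?(:[0-9]+)?$",
        body))[[1L]]
      if (length(m) == 0L || m[1] != body)
        perr(i, sprintf("malformed bracket atom '[%s]'", body))
      if (nzchar(m[2]))
        perr(i, "isotope specifications are unsupported")
      sym <- m[3]
      arom <- sym %in% .AROMATIC_OK
      el <- if (arom) toupper(sym) else sym
      if (!el %in% .ORGANIC_SUBSET)
        stop(sprintf("unsupported element '%s' in SMILES '%s'", el, text),
             call. = FALSE)
      hc <- 0L
      if (nzchar(m[5])) hc <- if (nzchar(m[6])) as.integer(m[6]) else 1L
      chg <- 0L
      cs <- m[7]
      if (!is.na(cs) && nzchar(cs)) {
        if (grepl("^[+-][0-9]+$", cs))
          chg <- as.integer(cs)
        else
          chg <- (nchar(gsub("-", "", cs)) - nchar(gsub("\\+", "", cs)))
      }
      emit_atom(el, arom, TRUE, hc, chg)
      i <- close_pos + 1L; next
    }
    # bare organic-subset atom (two-character Cl / Br first)
    two <- if (i < nc) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      emit_atom(two, FALSE, FALSE, NA_integer_, 0L); i <- i + 2L; next
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      emit_atom(ch, FALSE, FALSE, NA_integer_, 0L); i <- i + 1L; next
    }
    if (ch %in% .AROMATIC_OK) {
      emit_atom(toupper(ch), TRUE, FALSE, NA_integer_, 0L); i <- i + 1L; next
    }
    if (grepl("^[A-Z]", ch))
      stop(sprintf("unsupported element '%s%s' in SMILES '%s'",
                   ch, if (two %in% c("Cl", "Br")) "" else "", text),
           call. = FALSE)
    perr(i, sprintf("unexpected character '%s'", ch))
  }
  if (length(stack) > 0L) perr(nc, "unclosed branch '('")
  if (length(ring_atom) > 0L)
    perr(nc, sprintf("unclosed ring bond(s): %s",
                     paste(names(ring_atom), collapse = ", ")))
  if (!is.na(pending)) perr(nc, "dangling bond symbol")
  if (length(element) == 0L) perr(nc, "no atoms parsed")

  edges <- cbind(i = e_i, j = e_j)
  storage.mode(edges) <- "integer"
  n <- length(element)

  # implicit hydrogen counts
  bond_sum <- numeric(n); degree <- integer(n)
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      bond_sum[a] <- bond_sum[a] + e_ord[r]
      bond_sum[b] <- bond_sum[b] + e_ord[r]
      degree[a] <- degree[a] + 1L
      degree[b] <- degree[b] + 1L
    }
  }
  implicit_h <- integer(n)
  for (v in seq_len(n)) {
    if (bracket[v]) { implicit_h[v] <- bracket_h[v]; next }
    val <- .DEFAULT_VALENCE[[element[v]]]
    if (aromatic[v]) {
      # sp2 ring atom: one valence unit sits in the aromatic system
      h <- val - degree[v] - 1L
      if (h < 0L && element[v] %in% c("O", "S")) h <- 0L
    } else {
      h <- val - bond_sum[v]
    }
    if (h < 0L)
      stop(sprintf(
        "valence error at atom %d (%s) in '%s': computed hydrogen count %d",
        v, element[v], text, as.integer(h)), call. = FALSE)
    implicit_h[v] <- as.integer(h)
  }

  g <- new_molgraph(element, aromatic,
                    origin = rep("parsed", n),
                    edges = edges, bond_order = e_ord,
                    implicit_h = implicit_h,
                    name = name, smiles = text)
  if (!is_connected_graph(g))
    stop(sprintf("SMILES '%s' parsed to a disconnected graph", text),
         call. = FALSE)
  g
}

is_connected_graph <- function(g) {
  n <- n_atoms(g)
  if (n <= 1L) return(TRUE)
  adj <- vector("list", n)
  if (nrow(g$edges) > 0L) {
    for (r in seq_len(nrow(g$edges))) {
      a <- g$edges[r, 1L]; b <- g$edges[r, 2L]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- logical(n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

#' Add explicit hydrogen atoms to a parsed molecular graph
#'
#' Each heavy atom gains its implicit hydrogen count as degree-1 nodes.
#' Hydrogens are appended after all heavy atoms, in owner-atom order, so
#' node numbering (and hence the adjacency matrix) is deterministic.
#'
#' @param g a hydrogen-suppressed \code{molgraph} from [parse_smiles()]
#' @return a \code{molgraph} with explicit hydrogens and no remaining
#'   implicit counts.
#' @examples
#' n_atoms(hydrogenate(parse_smiles("CC")))  # ethane: 8 atoms
#' @export
hydrogenate <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  if (any(g$origin == "added-hydrogen"))
    stop("graph already carries explicit hydrogens", call. = FALSE)
  nh <- g$implicit_h
  n <- n_atoms(g)
  total_h <- sum(nh)
  element <- c(g$element, rep("H", total_h))
  aromatic <- c(g$aromatic, rep(FALSE, total_h))
  origin <- c(g$origin, rep("added-hydrogen", total_h))
  new_i <- integer(total_h); new_j <- integer(total_h)
  k <- 0L
  for (v in seq_len(n)) {
    if (nh[v] == 0L) next
    for (h in seq_len(nh[v])) {
      k <- k + 1L
      new_i[k] <- v
      new_j[k] <- n + k
    }
  }
  edges <- rbind(g$edges, cbind(i = new_i, j = new_j))
  storage.mode(edges) <- "integer"
  new_molgraph(element, aromatic, origin, edges,
               bond_order = c(g$bond_order, rep(1, total_h)),
               implicit_h = rep(0L, n + total_h),
               name = g$name, smiles = g$smiles)
}

#' Adjacency matrix of a molecular graph
#'
#' @param g a \code{molgraph}
#' @return symmetric 0/1 integer matrix with zero diagonal; row sums equal
#'   node degrees.
#' @examples
#' adjacency_matrix(parse_smiles("CC"))
#' @export
adjacency_matrix <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  n <- n_atoms(g)
  a <- matrix(0L, n, n)
  if (nrow(g$edges) > 0L) {
    a[g$edges] <- 1L
    a[g$edges[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  a
}

#' Molecular formula of a graph
#'
#' Counts atoms by element (implicit hydrogens included for suppressed
#' graphs), in Hill order (C, H, then alphabetical).
#'
#' @param g a \code{molgraph}
#' @return a named integer vector of element counts.
#' @export
molecular_formula <- function(g) {
  counts <- table(g$element)
  counts <- stats::setNames(as.integer(counts), names(counts))
  imp <- sum(g$implicit_h)
  if (imp > 0L) counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + imp
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  counts[ord]
}

#' Read a .smi file
#'
#' One record per line: \code{SMILES<whitespace>name}; the name is optional.
#'
#' @param path path to a .smi text file
#' @return data.frame with columns \code{smiles} and \code{name}.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  data.frame(smiles = vapply(parts, `[`, "", 1L),
             name = vapply(parts, function(p)
               if (length(p) > 1L) paste(p[-1L], collapse = " ") else NA_character_,
               ""),
             stringsAsFactors = FALSE)
}

#' Write a .smi file
#'
#' @param df data.frame with columns \code{smiles} and \code{name}
#' @param path output path
#' @return invisibly, \code{path}.
#' @export
write_smi <- function(df, path) {
  stopifnot(all(c("smiles", "name") %in% names(df)))
  writeLines(paste(df$smiles, df$name), path)
  invisible(path)
}
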