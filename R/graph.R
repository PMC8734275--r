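#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select distinct arrange bind_rows left_join
#'   inner_join rename group_by summarise ungroup pull across all_of n
NULL

#' Default namespace prefixes
#'
#' The prefix map bound to every [prov_graph()]: the experiment-provenance
#' vocabulary under `repr` (<https://w3id.org/reproduceme#>), the W3C PROV-O
#' namespace, P-Plan, and the usual RDF/RDFS/OWL/XSD machinery.
#'
#' @return A named character vector mapping prefix to namespace IRI.
#' @export
#' @examples
#' prov_prefixes()["repr"]
prov_prefixes <- function() {
  c(
    repr      = "https://w3id.org/reproduceme#",
    prov      = "http://www.w3.org/ns/prov#",
    `p-plan`  = "http://purl.org/net/p-plan#",
    rdf       = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs      = "http://www.w3.org/2000/01/rdf-schema#",
    owl       = "http://www.w3.org/2002/07/owl#",
    xsd       = "http://www.w3.org/2001/XMLSchema#",
    dcterms   = "http://purl.org/dc/terms/"
  )
}

empty_triples <- function() {
  tibble(
    subject = character(), predicate = character(), object = character(),
    literal = logical(), datatype = character(), lang = character()
  )
}

#' Create a provenance graph
#'
#' A `prov_graph` is a set of RDF triples held as a tibble with columns
#' `subject`, `predicate`, `object` (all expanded IRIs, or literal lexical
#' forms), `literal` (logical), `datatype` and `lang`, plus a prefix map used
#' for CURIE expansion and serialization.
#'
#' @param triples A tibble of triples, or `NULL` for an empty graph. CURIEs
#'   in subject/predicate/object (and `datatype`) are expanded on entry.
#' @param prefixes Named character vector of prefix -> namespace bindings.
#' @return An object of class `prov_graph`.
#' @export
#' @examples
#' g <- prov_graph(tibble::tibble(
#'   subject = "ex:thing", predicate = "rdf:type", object = "prov:Entity",
#'   literal = FALSE, datatype = NA_character_, lang = NA_character_
#' ), prefixes = c(prov_prefixes(), ex = "https://example.org/"))
#' n_triples(g)
prov_graph <- function(triples = NULL, prefixes = prov_prefixes()) {
  if (is.null(triples)) triples <- empty_triples()
  triples <- as_tibble(triples)
  need <- c("subject", "predicate", "object")
  if (!all(need %in% names(triples))) {
    abort("triples must have columns subject, predicate, object")
  }
  if (!"literal" %in% names(triples)) triples$literal <- FALSE
  if (!"datatype" %in% names(triples)) triples$datatype <- NA_character_
  if (!"lang" %in% names(triples)) triples$lang <- NA_character_
  triples <- triples[, c("subject", "predicate", "object", "literal", "datatype", "lang")]
  if (nrow(triples) > 0) {
    triples$subject <- expand_curie(triples$subject, prefixes)
    triples$predicate <- expand_curie(triples$predicate, prefixes)
    triples$object <- ifelse(triples$literal, triples$object,
                             expand_curie(triples$object, prefixes))
    triples$datatype <- expand_curie(triples$datatype, prefixes)
  }
  g <- structure(list(triples = distinct(triples), prefixes = prefixes),
                 class = "prov_graph")
  g
}

#' @export
print.prov_graph <- function(x, ...) {
  cat("<prov_graph> ", nrow(x$triples), " triples, ",
      length(x$prefixes), " prefixes\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Number of triples in a graph
#' @param g A [prov_graph()].
#' @return Integer count of distinct triples.
#' @export
n_triples <- function(g) nrow(g$triples)

#' Add triples to a graph
#'
#' @param g A [prov_graph()].
#' @param triples Tibble of triples (CURIEs allowed; expanded on entry).
#' @return The graph with the triples merged in (set semantics).
#' @export
add_triples <- function(g, triples) {
  stopifnot(inherits(g, "prov_graph"))
  g2 <- prov_graph(triples, g$prefixes)
  g$triples <- distinct(bind_rows(g$triples, g2$triples))
  g
}

#' Merge two provenance graphs
#' @param a,b Graphs; prefixes are unioned (first binding wins).
#' @return The union graph.
#' @export
graph_union <- function(a, b) {
  pref <- c(a$prefixes, b$prefixes[!names(b$prefixes) %in% names(a$prefixes)])
  structure(list(triples = distinct(bind_rows(a$triples, b$triples)),
                 prefixes = pref),
            class = "prov_graph")
}

# --- triple construction helpers (internal) --------------------------------

spo <- function(s, p, o) {
  tibble(subject = s, predicate = p, object = o,
         literal = FALSE, datatype = NA_character_, lang = NA_character_)
}

spv <- function(s, p, value, datatype = NA_character_) {
  tibble(subject = s, predicate = p, object = as.character(value),
         literal = TRUE, datatype = datatype, lang = NA_character_)
}

# --- CURIE handling ---------------------------------------------------------

#' Expand CURIEs against a prefix map
#'
#' Strings of the form `prefix:local` whose prefix is bound are expanded to
#' full IRIs; full IRIs, blank-node labels (`_:b`), and unbound strings pass
#' through unchanged. Vectorized; NA-safe.
#'
#' @param x Character vector of CURIEs or IRIs.
#' @param prefixes Named character vector of bindings.
#' @return Character vector of IRIs.
#' @export
expand_curie <- function(x, prefixes = prov_prefixes()) {
  if (length(x) == 0) return(x)
  out <- x
  m <- stringr::str_match(x, "^([A-Za-z][A-Za-z0-9_.-]*):(.*)$")
  hit <- !is.na(m[, 1]) & m[, 2] %in% names(prefixes) &
    !stringr::str_detect(x, "^(https?|urn|file|mailto):")
  out[hit] <- paste0(prefixes[m[hit, 2]], m[hit, 3])
  out
}

#' Compact IRIs to CURIEs where a prefix matches
#'
#' @inheritParams expand_curie
#' @return Character vector; IRIs under a bound namespace become
#'   `prefix:local` when the local part is a simple name, others unchanged.
#' @export
compact_iri <- function(x, prefixes = prov_prefixes()) {
  if (length(x) == 0) return(x)
  out <- x
  ord <- order(-nchar(prefixes))  # longest namespace first
  for (i in ord) {
    ns <- prefixes[i]
    pfx <- names(prefixes)[i]
    idx <- !is.na(out) & startsWith(out, ns) & out == x  # only untouched
    local <- substring(out[idx], nchar(ns) + 1L)
    ok <- stringr::str_detect(local, "^[A-Za-z_][A-Za-z0-9_-]*$")
    out[idx][ok] <- paste0(pfx, ":", local[ok])
  }
  out
}

# --- tidy/glance ------------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a provenance graph into a triple tibble
#'
#' @param x A [prov_graph()].
#' @param compact Compact IRIs to CURIEs for readability (default TRUE).
#' @param ... Unused.
#' @return A tibble with one row per triple.
#' @method tidy prov_graph
#' @export
tidy.prov_graph <- function(x, compact = TRUE, ...) {
  tr <- x$triples
  if (compact) {
    tr$subject <- compact_iri(tr$subject, x$prefixes)
    tr$predicate <- compact_iri(tr$predicate, x$prefixes)
    tr$object <- ifelse(tr$literal, tr$object, compact_iri(tr$object, x$prefixes))
    tr$datatype <- compact_iri(tr$datatype, x$prefixes)
  }
  arrange(tr, .data$subject, .data$predicate, .data$object)
}

#' One-row summary of a provenance graph
#' @param x A [prov_graph()].
#' @param ... Unused.
#' @return Tibble with triple, subject, and predicate counts.
#' @method glance prov_graph
#' @export
glance.prov_graph <- function(x, ...) {
  tibble(
    n_triples = nrow(x$triples),
    n_subjects = dplyr::n_distinct(x$triples$subject),
    n_predicates = dplyr::n_distinct(x$triples$predicate),
    n_prefixes = length(x$prefixes)
  )
}

# --- equality / isomorphism -------------------------------------------------

canonical_triple_key <- function(tr) {
  dt <- ifelse(is.na(tr$datatype), "", tr$datatype)
  lg <- ifelse(is.na(tr$lang), "", tr$lang)
  paste(tr$subject, tr$predicate, tr$object, tr$literal, dt, lg, sep = "\r")
}

is_blank <- function(x) startsWith(x, "_:")

#' Test two graphs for isomorphism
#'
#' Graphs without blank nodes are compared as triple sets. Blank nodes are
#' relabelled by iterative signature refinement (hash of incident ground
#' triples) before comparison, which is exact for the tree-shaped blank-node
#' structures produced by RDF serializations of this model.
#'
#' @param a,b [prov_graph()] objects.
#' @return TRUE if the graphs contain the same triples up to blank-node
#'   relabelling.
#' @export
graph_isomorphic <- function(a, b) {
  ta <- canonicalize_blanks(a$triples)
  tb <- canonicalize_blanks(b$triples)
  setequal(canonical_triple_key(ta), canonical_triple_key(tb))
}

canonicalize_blanks <- function(tr) {
  blanks <- unique(c(tr$subject[is_blank(tr$subject)],
                     tr$object[!tr$literal & is_blank(tr$object)]))
  if (length(blanks) == 0) return(tr)
  sig <- stats::setNames(rep("b", length(blanks)), blanks)
  for (i in 1:3) {
    newsig <- vapply(blanks, function(b) {
      rows_s <- tr[tr$subject == b, ]
      rows_o <- tr[!tr$literal & tr$object == b, ]
      out <- c(
        paste("S", rows_s$predicate,
              ifelse(!rows_s$literal & is_blank(rows_s$object),
                     sig[rows_s$object], rows_s$object)),
        paste("O", rows_o$predicate,
              ifelse(is_blank(rows_o$subject), sig[rows_o$subject], rows_o$subject))
      )
      digest::digest(sort(out))
    }, character(1))
    sig <- newsig
  }
  # disambiguate equal signatures deterministically
  lab <- paste0("_:c", as.integer(factor(rank(sig, ties.method = "first"))))
  names(lab) <- blanks
  tr$subject <- ifelse(is_blank(tr$subject), lab[tr$subject], tr$subject)
  tr$object <- ifelse(!tr$literal & is_blank(tr$object), lab[tr$object], tr$object)
  tr
}

# --- basic graph pattern matching ------------------------------------------

#' Match a basic graph pattern against a graph
#'
#' The query engine behind the competency questions: a pattern is a tibble of
#' triple patterns whose `s`/`p`/`o` entries are either constants (CURIEs or
#' IRIs, expanded against the graph's prefixes) or variables written `"?name"`.
#' Patterns are matched in order and joined on shared variables, exactly as a
#' SPARQL basic graph pattern would be.
#'
#' @param g A [prov_graph()].
#' @param patterns Tibble (or data frame) with columns `s`, `p`, `o`.
#' @return A tibble of variable bindings, one column per variable, one row
#'   per solution. Zero rows when the pattern has no match.
#' @export
#' @examples
#' g <- fixture_colocalization()
#' match_bgp(g, tibble::tibble(
#'   s = "?x", p = "rdf:type", o = "repr:Plasmid"
#' ))
match_bgp <- function(g, patterns) {
  stopifnot(inherits(g, "prov_graph"))
  patterns <- as_tibble(patterns)
  stopifnot(all(c("s", "p", "o") %in% names(patterns)))
  bindings <- NULL
  for (i in seq_len(nrow(patterns))) {
    pat <- patterns[i, ]
    sol <- match_one_pattern(g, pat$s, pat$p, pat$o)
    if (is.null(bindings)) {
      bindings <- sol
    } else {
      shared <- intersect(names(bindings), names(sol))
      if (length(shared) > 0) {
        bindings <- inner_join(bindings, sol, by = shared,
                               relationship = "many-to-many")
      } else {
        bindings <- dplyr::cross_join(bindings, sol)
      }
    }
    if (nrow(bindings) == 0) break
  }
  distinct(bindings %||% tibble())
}

is_var <- function(x) !is.na(x) & startsWith(x, "?")

strip_angles <- function(x) sub("^<(.*)>$", "\\1", x)

match_one_pattern <- function(g, s, p, o) {
  tr <- g$triples
  pf <- g$prefixes
  if (!is_var(s)) tr <- tr[tr$subject == expand_curie(strip_angles(s), pf), ]
  if (!is_var(p)) tr <- tr[tr$predicate == expand_curie(strip_angles(p), pf), ]
  if (!is_var(o)) {
    oe <- expand_curie(strip_angles(o), pf)
    tr <- tr[(tr$literal & tr$object == o) | (!tr$literal & tr$object == oe), ]
  }
  out <- list()
  if (is_var(s)) out[[substring(s, 2)]] <- tr$subject
  if (is_var(p)) out[[substring(p, 2)]] <- tr$predicate
  if (is_var(o)) out[[substring(o, 2)]] <- tr$object
  if (length(out) == 0) {
    # all-constant pattern: acts as an existence filter
    return(tibble(.keep = logical(nrow(tr)))[seq_len(min(nrow(tr), 1)), 0])
  }
  distinct(as_tibble(out))
}

# objects of a predicate for a subject (expanded IRIs in, raw values out)
obj_of <- function(g, s, p, literal = NA) {
  tr <- g$triples
  rows <- tr$subject == s & tr$predicate == expand_curie(p, g$prefixes)
  if (!is.na(literal)) rows <- rows & tr$literal == literal
  tr$object[rows]
}

obj_of1 <- function(g, s, p, literal = NA) {
  v <- obj_of(g, s, p, literal)
  if (length(v) == 0) NA_character_ else v[[1]]
}
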