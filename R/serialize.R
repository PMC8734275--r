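# RDF serialization: Turtle, N3 (emitted as the shared Turtle subset) and
# RDF/XML. The environment offers no RDF stack for R, so reading and writing
# are implemented here for the subset of the syntaxes this model emits:
# IRIs, prefixed names, blank node labels, plain/typed/language literals
# (including multi-line long strings), predicate-object lists.

SUPPORTED_DIALECTS <- c("turtle", "n3", "rdfxml")

check_dialect <- function(dialect) {
  dialect <- match.arg(dialect, SUPPORTED_DIALECTS)
  dialect
}

#' Serialize a provenance graph
#'
#' @param g A [prov_graph()].
#' @param dialect One of `"turtle"`, `"n3"`, `"rdfxml"`. The N3 output is the
#'   Turtle-compatible subset of N3 (every emitted document is valid in both).
#' @param file Optional path; when given the document is written there and the
#'   path returned invisibly.
#' @return The serialized document as a single string (unless `file` is set).
#' @export
rdf_serialize <- function(g, dialect = c("turtle", "n3", "rdfxml"), file = NULL) {
  stopifnot(inherits(g, "prov_graph"))
  dialect <- check_dialect(dialect[[1]])
  doc <- switch(dialect,
    turtle = write_turtle(g),
    n3 = write_turtle(g),
    rdfxml = write_rdfxml(g)
  )
  if (!is.null(file)) {
    writeLines(doc, file, useBytes = TRUE)
    return(invisible(file))
  }
  doc
}

#' Parse an RDF document into a provenance graph
#'
#' @param x A document string or a path to a file.
#' @param dialect One of `"turtle"`, `"n3"`, `"rdfxml"`.
#' @param prefixes Extra prefix bindings merged with those declared in the
#'   document.
#' @return A [prov_graph()].
#' @export
rdf_parse <- function(x, dialect = c("turtle", "n3", "rdfxml"),
                      prefixes = prov_prefixes()) {
  dialect <- check_dialect(dialect[[1]])
  if (length(x) == 1 && !grepl("[\n<@]", x) && file.exists(x)) {
    x <- paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else {
    x <- paste(x, collapse = "\n")
  }
  switch(dialect,
    turtle = parse_turtle(x, prefixes),
    n3 = parse_turtle(x, prefixes),
    rdfxml = parse_rdfxml(x, prefixes)
  )
}

# --- Turtle writer ----------------------------------------------------------

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x
}

fmt_literal <- function(value, datatype, lang, prefixes) {
  esc <- escape_literal(value)
  quoted <- ifelse(
    grepl("\n", value, fixed = TRUE),
    paste0('"""', esc, '"""'),
    paste0('"', gsub("\n", "\\n", esc, fixed = TRUE), '"')
  )
  out <- quoted
  has_dt <- !is.na(datatype)
  out[has_dt] <- paste0(quoted[has_dt], "^^",
                        fmt_term(datatype[has_dt], prefixes))
  has_lang <- !is.na(lang) & !has_dt
  out[has_lang] <- paste0(quoted[has_lang], "@", lang[has_lang])
  out
}

fmt_term <- function(iri, prefixes) {
  out <- compact_iri(iri, prefixes)
  bare <- out == iri & !is_blank(iri)
  out[bare] <- paste0("<", iri[bare], ">")
  out
}

write_turtle <- function(g) {
  pf <- g$prefixes
  header <- paste0("@prefix ", names(pf), ": <", pf, "> .")
  tr <- g$triples
  if (nrow(tr) == 0) return(paste(c(header, ""), collapse = "\n"))
  tr <- arrange(tr, .data$subject, .data$predicate, .data$object)
  s_fmt <- fmt_term(tr$subject, pf)
  p_fmt <- fmt_term(tr$predicate, pf)
  p_fmt[tr$predicate == expand_curie("rdf:type", pf)] <- "a"
  o_fmt <- ifelse(tr$literal,
                  fmt_literal(tr$object, tr$datatype, tr$lang, pf),
                  fmt_term(tr$object, pf))
  blocks <- vapply(split(seq_len(nrow(tr)), factor(s_fmt, levels = unique(s_fmt))),
    function(idx) {
      po <- vapply(split(idx, factor(p_fmt[idx], levels = unique(p_fmt[idx]))),
        function(j) paste0(p_fmt[j[1]], " ", paste(o_fmt[j], collapse = ", ")),
        character(1))
      paste0(s_fmt[idx[1]], " ", paste(po, collapse = " ;\n    "), " .")
    }, character(1))
  paste(c(header, "", blocks, ""), collapse = "\n")
}

# --- Turtle tokenizer/parser ------------------------------------------------

TOKEN_RE <- paste0(
  '"""(?s:.*?)"""',                             # long string
  '|"(?:[^"\\\\\n]|\\\\.)*"',                   # string
  "|<[^<>\"{}|^`\\\\ ]*>",                      # IRIREF
  "|@prefix|@base",                             # directives
  "|@[A-Za-z]+(?:-[A-Za-z0-9]+)*",              # langtag
  "|\\^\\^",                                    # datatype marker
  "|_:[A-Za-z0-9_]+",                           # blank node label
  "|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z_][A-Za-z0-9_.-]*", # prefixed name
  "|[A-Za-z][A-Za-z0-9_.-]*:",                  # prefix-only (declarations)
  "|[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?", # numeric
  "|\\ba\\b|\\btrue\\b|\\bfalse\\b",
  "|[;,.\\[\\]()]"
)

tokenize_turtle <- function(doc) {
  # strip comments outside of strings: remove '#' to end of line when the '#'
  # is not inside a quoted region; handled by tokenizing with the master regex
  # (strings are matched atomically) and dropping nothing else.
  m <- gregexpr(TOKEN_RE, doc, perl = TRUE)[[1]]
  if (m[1] == -1) return(character(0))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  toks <- substring(doc, starts, starts + lens - 1)
  # discard tokens that begin inside a comment: rebuild comment spans
  keep <- rep(TRUE, length(toks))
  # find comment regions: '#' not preceded inside a token match
  covered <- logical(nchar(doc))
  for (i in seq_along(starts)) covered[starts[i]:(starts[i] + lens[i] - 1)] <- TRUE
  chars <- strsplit(doc, "", fixed = TRUE)[[1]]
  in_comment <- FALSE
  comment <- logical(length(chars))
  for (i in seq_along(chars)) {
    if (!in_comment && chars[i] == "#" && !covered[i]) in_comment <- TRUE
    if (in_comment && chars[i] == "\n") in_comment <- FALSE
    comment[i] <- in_comment
  }
  keep <- !comment[starts]
  toks[keep]
}

unescape_literal <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

parse_turtle <- function(doc, prefixes = prov_prefixes()) {
  toks <- tokenize_turtle(doc)
  pf <- prefixes
  xsd <- prov_prefixes()[["xsd"]]
  acc_s <- character(0); acc_p <- character(0); acc_o <- character(0)
  acc_lit <- logical(0); acc_dt <- character(0); acc_lang <- character(0)
  i <- 1L
  n <- length(toks)
  fail <- function(msg, at) {
    abort(sprintf("Turtle parse error near token %d ('%s'): %s",
                  at, if (at <= n) toks[at] else "<eof>", msg))
  }
  resolve <- function(tok, at) {
    if (startsWith(tok, "<")) return(substr(tok, 2, nchar(tok) - 1))
    if (startsWith(tok, "_:")) return(tok)
    if (tok == "a") return(expand_curie("rdf:type", prov_prefixes()))
    m <- stringr::str_match(tok, "^([A-Za-z][A-Za-z0-9_.-]*):(.*)$")
    if (!is.na(m[1, 1])) {
      if (!m[1, 2] %in% names(pf)) fail(paste0("unbound prefix '", m[1, 2], "'"), at)
      return(paste0(pf[[m[1, 2]]], m[1, 3]))
    }
    fail("expected IRI, prefixed name or blank node", at)
  }
  read_object <- function() {
    tok <- toks[i]
    if (startsWith(tok, '"')) {
      if (startsWith(tok, '"""')) {
        val <- substr(tok, 4, nchar(tok) - 3)
      } else {
        val <- substr(tok, 2, nchar(tok) - 1)
      }
      val <- unescape_literal(val)
      i <<- i + 1L
      dt <- NA_character_; lang <- NA_character_
      if (i <= n && toks[i] == "^^") {
        i <<- i + 1L
        dt <- resolve(toks[i], i); i <<- i + 1L
      } else if (i <= n && grepl("^@[A-Za-z]", toks[i]) &&
                 !toks[i] %in% c("@prefix", "@base")) {
        lang <- substring(toks[i], 2); i <<- i + 1L
      }
      list(o = val, literal = TRUE, dt = dt, lang = lang)
    } else if (grepl("^[+-]?[0-9]", tok)) {
      i <<- i + 1L
      dt <- if (grepl("[.eE]", tok)) paste0(xsd, "decimal") else paste0(xsd, "integer")
      list(o = tok, literal = TRUE, dt = dt, lang = NA_character_)
    } else if (tok %in% c("true", "false")) {
      i <<- i + 1L
      list(o = tok, literal = TRUE, dt = paste0(xsd, "boolean"), lang = NA_character_)
    } else {
      o <- resolve(tok, i); i <<- i + 1L
      list(o = o, literal = FALSE, dt = NA_character_, lang = NA_character_)
    }
  }
  while (i <= n) {
    tok <- toks[i]
    if (tok == "@prefix") {
      if (i + 2 > n) fail("truncated @prefix", i)
      pname <- toks[i + 1]
      if (!grepl(":$", pname)) fail("expected prefix name", i + 1)
      iritok <- toks[i + 2]
      if (!startsWith(iritok, "<")) fail("expected namespace IRI", i + 2)
      pf[[sub(":$", "", pname)]] <- substr(iritok, 2, nchar(iritok) - 1)
      i <- i + 3L
      if (i <= n && toks[i] == ".") i <- i + 1L else fail("expected '.'", i)
      next
    }
    if (tok == "@base") { i <- i + 2L; if (i <= n && toks[i] == ".") i <- i + 1L; next }
    s <- resolve(tok, i); i <- i + 1L
    repeat {
      if (i > n) fail("unterminated statement", i)
      p <- resolve(toks[i], i); i <- i + 1L
      repeat {
        if (i > n) fail("missing object", i)
        ob <- read_object()
        acc_s <- c(acc_s, s); acc_p <- c(acc_p, p); acc_o <- c(acc_o, ob$o)
        acc_lit <- c(acc_lit, ob$literal); acc_dt <- c(acc_dt, ob$dt)
        acc_lang <- c(acc_lang, ob$lang)
        if (i <= n && toks[i] == ",") { i <- i + 1L; next }
        break
      }
      if (i <= n && toks[i] == ";") {
        i <- i + 1L
        # tolerate trailing ';' before '.'
        if (i <= n && toks[i] == ".") { i <- i + 1L; break }
        next
      }
      if (i <= n && toks[i] == ".") { i <- i + 1L; break }
      fail("expected ';', ',' or '.'", i)
    }
  }
  prov_graph(
    tibble(subject = acc_s, predicate = acc_p, object = acc_o,
           literal = acc_lit, datatype = acc_dt, lang = acc_lang),
    prefixes = pf
  )
}

# --- RDF/XML ----------------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# XML QNames cannot start local parts with a digit and (for property
# elements) require a bound prefix; every predicate this model emits is
# compactable under the default prefixes.
qname_or_stop <- function(iri, prefixes) {
  q <- compact_iri(iri, prefixes)
  if (identical(q, iri)) {
    abort(sprintf("predicate <%s> is not compactable under the bound prefixes (required for RDF/XML)", iri))
  }
  q
}

write_rdfxml <- function(g) {
  pf <- g$prefixes
  tr <- arrange(g$triples, .data$subject, .data$predicate, .data$object)
  xmlns <- paste0('xmlns:', names(pf), '="', xml_escape(pf), '"', collapse = "\n         ")
  body <- character(0)
  for (s in unique(tr$subject)) {
    rows <- tr[tr$subject == s, ]
    about <- if (is_blank(s)) {
      paste0('rdf:nodeID="', substring(s, 3), '"')
    } else {
      paste0('rdf:about="', xml_escape(s), '"')
    }
    props <- vapply(seq_len(nrow(rows)), function(i) {
      q <- qname_or_stop(rows$predicate[i], pf)
      if (rows$literal[i]) {
        attrs <- ""
        if (!is.na(rows$datatype[i])) {
          attrs <- paste0(' rdf:datatype="', xml_escape(rows$datatype[i]), '"')
        } else if (!is.na(rows$lang[i])) {
          attrs <- paste0(' xml:lang="', rows$lang[i], '"')
        }
        paste0("    <", q, attrs, ">", xml_escape(rows$object[i]), "</", q, ">")
      } else if (is_blank(rows$object[i])) {
        paste0("    <", q, ' rdf:nodeID="', substring(rows$object[i], 3), '"/>')
      } else {
        paste0("    <", q, ' rdf:resource="', xml_escape(rows$object[i]), '"/>')
      }
    }, character(1))
    body <- c(body, paste0('  <rdf:Description ', about, '>'), props,
              "  </rdf:Description>")
  }
  paste(c('<?xml version="1.0" encoding="UTF-8"?>',
          paste0("<rdf:RDF ", xmlns, ">"), body, "</rdf:RDF>", ""),
        collapse = "\n")
}

parse_rdfxml <- function(doc, prefixes = prov_prefixes()) {
  xml <- tryCatch(suppressWarnings(xml2::read_xml(doc)),
                  error = function(e) abort(paste("RDF/XML parse error:", conditionMessage(e))))
  ns <- xml2::xml_ns(xml)
  pf <- stats::setNames(as.character(ns), names(ns))
  # xml2 prefixes d1, d2 for default namespaces; merge with caller bindings
  pf <- c(prefixes, pf[!pf %in% prefixes])
  rdf_ns <- prov_prefixes()[["rdf"]]
  acc <- list()
  descs <- xml2::xml_find_all(xml, "./*")
  for (d in descs) {
    node_iri <- node_identity(d, rdf_ns)
    s <- node_iri
    # typed node element (not rdf:Description) contributes an rdf:type triple
    qn <- xml2::xml_name(d, ns)
    full <- resolve_xml_qname(qn, ns)
    if (!identical(full, paste0(rdf_ns, "Description"))) {
      acc[[length(acc) + 1]] <- spo(s, paste0(rdf_ns, "type"), full)
    }
    for (p in xml2::xml_find_all(d, "./*")) {
      pred <- resolve_xml_qname(xml2::xml_name(p, ns), ns)
      res <- xml2::xml_attr(p, "resource")
      nid <- xml2::xml_attr(p, "nodeID")
      if (!is.na(res)) {
        acc[[length(acc) + 1]] <- spo(s, pred, res)
      } else if (!is.na(nid)) {
        acc[[length(acc) + 1]] <- spo(s, pred, paste0("_:", nid))
      } else {
        dt <- xml2::xml_attr(p, "datatype")
        lang <- xml2::xml_attr(p, "lang")
        acc[[length(acc) + 1]] <- tibble(
          subject = s, predicate = pred, object = xml2::xml_text(p),
          literal = TRUE, datatype = ifelse(is.na(dt), NA_character_, dt),
          lang = ifelse(is.na(lang), NA_character_, lang)
        )
      }
    }
  }
  triples <- if (length(acc)) bind_rows(acc) else empty_triples()
  keep <- names(pf) != "" & !duplicated(names(pf))
  prov_graph(triples, prefixes = pf[keep])
}

node_identity <- function(d, rdf_ns) {
  about <- xml2::xml_attr(d, "about")
  nid <- xml2::xml_attr(d, "nodeID")
  if (!is.na(about)) about
  else if (!is.na(nid)) paste0("_:", nid)
  else paste0("_:g", digest::digest(xml2::xml_path(d)))
}

resolve_xml_qname <- function(qn, ns) {
  parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
  if (length(parts) == 2 && parts[1] %in% names(ns)) {
    paste0(ns[[parts[1]]], parts[2])
  } else {
    qn
  }
}
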