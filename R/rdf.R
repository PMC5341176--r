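# Triple-graph view of the annotation store and its Turtle / N-Triples
# serializations. The graph is blank-node-free: annotation, target, selector
# and body nodes all get URIs minted from the annotation uid, which keeps
# graph/relational set equality decidable. The writer/parser cover exactly the
# subset this module emits (full-URI subjects/objects, prefixed predicates,
# plain string literals).

uri_annotation <- function(uid) paste0(NS_OHDSI, "annotation/", uid)
uri_target <- function(uid) paste0(NS_OHDSI, "target/", uid)
uri_selector <- function(uid) paste0(NS_OHDSI, "selector/", uid)
uri_body <- function(uid, i) paste0(NS_OHDSI, "body/", uid, "/", i)
uri_concept <- function(concept_id) paste0(NS_OHDSI, concept_id)

# expand "ohdsi:Foo" registry types to full URIs
expand_curie <- function(x) {
  sub("^ohdsi:", NS_OHDSI, sub("^oa:", NS_OA, x))
}

triple_df <- function(subject = character(0), predicate = character(0),
                      object = character(0), object_type = character(0)) {
  data.frame(subject = subject, predicate = predicate, object = object,
             object_type = object_type)
}

#' Emit the triple graph of one annotation
#'
#' Exactly: a typing triple, `oa:hasTarget`, the target's `oa:hasSource` and
#' selector triples, and per body `oa:hasBody` plus the body's
#' `ohdsi:ImedsDrug`, `ohdsi:ImedsHoi` and evidence-type triples. The triple
#' count is thus a fixed function of the body and selector-field counts:
#' `3 + 4 * n_bodies + (n_selector_fields > 0) + n_selector_fields`.
#'
#' @param annotation an `oa_annotation`.
#' @return Data frame with columns `subject`, `predicate`, `object`,
#'   `object_type` (`"uri"` or `"literal"`).
#' @export
to_triples <- function(annotation) {
  a <- annotation
  uid <- a$annotation_uid
  ann <- uri_annotation(uid)
  tgt <- uri_target(uid)
  rows <- list(
    triple_df(ann, paste0(NS_RDF, "type"), expand_curie(a$annotation_type), "uri"),
    triple_df(ann, paste0(NS_OA, "hasTarget"), tgt, "uri"),
    triple_df(tgt, paste0(NS_OA, "hasSource"), a$target$source_document_uri, "uri")
  )
  sel <- a$target$selector
  if (length(sel) > 0) {
    sel_uri <- uri_selector(uid)
    rows[[length(rows) + 1]] <- triple_df(tgt, paste0(NS_OA, "hasSelector"), sel_uri, "uri")
    if (!is.null(sel$exact_text)) {
      rows[[length(rows) + 1]] <- triple_df(sel_uri, paste0(NS_OA, "exact"),
                                            sel$exact_text, "literal")
    }
    if (!is.null(sel$section)) {
      rows[[length(rows) + 1]] <- triple_df(sel_uri, paste0(NS_OHDSI, "section"),
                                            sel$section, "literal")
    }
  }
  for (i in seq_along(a$bodies)) {
    b <- a$bodies[[i]]
    bdy <- uri_body(uid, i)
    rows[[length(rows) + 1]] <- triple_df(ann, paste0(NS_OA, "hasBody"), bdy, "uri")
    rows[[length(rows) + 1]] <- triple_df(bdy, paste0(NS_OHDSI, "ImedsDrug"),
                                          uri_concept(b$drug_concept_id), "uri")
    rows[[length(rows) + 1]] <- triple_df(bdy, paste0(NS_OHDSI, "ImedsHoi"),
                                          uri_concept(b$hoi_concept_id), "uri")
    rows[[length(rows) + 1]] <- triple_df(bdy, paste0(NS_OHDSI, "evidenceType"),
                                          b$evidence_type, "literal")
  }
  do.call(rbind, rows)
}

#' Serialize the whole store as one triple graph
#' @param store an `evidence_store`.
#' @return Triple data frame (union over all annotations).
#' @export
store_to_graph <- function(store) {
  if (length(store$annotations) == 0) return(triple_df())
  uids <- sort(as.integer(names(store$annotations)))
  do.call(rbind, lapply(as.character(uids), function(k) to_triples(store$annotations[[k]])))
}

#' Rebuild the store graph from the relational rows only
#'
#' Ignores the in-memory annotation objects; used to check graph/relational
#' duality.
#' @param store an `evidence_store`.
#' @return Triple data frame.
#' @export
graph_from_relational <- function(store) {
  anns <- rebuild_all_annotations(store)
  if (length(anns) == 0) return(triple_df())
  uids <- sort(as.integer(names(anns)))
  do.call(rbind, lapply(as.character(uids), function(k) to_triples(anns[[k]])))
}

# canonical form for set comparison
graph_canonical <- function(graph) {
  key <- paste(graph$subject, graph$predicate, graph$object, graph$object_type,
               sep = "\r")
  sort(unique(key))
}

#' Compare two triple graphs as sets
#' @param a,b triple data frames.
#' @return `TRUE` when equal as sets of triples.
#' @export
graphs_equal <- function(a, b) {
  identical(graph_canonical(a), graph_canonical(b))
}

escape_literal <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  x <- gsub("\n", "\\\\n", x)
  gsub("\t", "\\\\t", x)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "")[[1]]
    buf <- character(0)
    j <- 1
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        nxt <- chars[j + 1]
        buf <- c(buf, switch(nxt, n = "\n", t = "\t", "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2
      } else {
        buf <- c(buf, chars[j])
        j <- j + 1
      }
    }
    out[i] <- paste(buf, collapse = "")
  }
  out
}

term_out <- function(value, type, prefixes = NULL) {
  if (type == "literal") return(paste0("\"", escape_literal(value), "\""))
  if (!is.null(prefixes)) {
    for (p in names(prefixes)) {
      ns <- prefixes[[p]]
      if (startsWith(value, ns)) {
        local <- substring(value, nchar(ns) + 1)
        if (grepl("^[A-Za-z0-9_-]+$", local)) return(paste0(p, ":", local))
      }
    }
  }
  paste0("<", value, ">")
}

#' Write a triple graph as Turtle
#'
#' Canonical serialization: prefix declarations for `oa:`, `ohdsi:` and
#' `rdf:`, then one sorted triple per line; URIs are prefixed only when the
#' local part is prefix-safe, otherwise written in full.
#'
#' @param graph triple data frame (from [to_triples()] / [store_to_graph()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_turtle <- function(graph, path) {
  prefixes <- c(oa = NS_OA, ohdsi = NS_OHDSI, rdf = NS_RDF)
  graph <- graph[order(graph$subject, graph$predicate, graph$object), , drop = FALSE]
  lines <- c(
    vapply(names(prefixes), function(p)
      paste0("@prefix ", p, ": <", prefixes[[p]], "> ."), ""),
    "",
    vapply(seq_len(nrow(graph)), function(i) {
      paste(term_out(graph$subject[i], "uri", prefixes),
            term_out(graph$predicate[i], "uri", prefixes),
            term_out(graph$object[i], graph$object_type[i], prefixes),
            ".")
    }, "")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a triple graph as N-Triples
#'
#' Diff-friendly output: full URIs, one sorted triple per line, no prefixes.
#' @param graph triple data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ntriples <- function(graph, path) {
  graph <- graph[order(graph$subject, graph$predicate, graph$object), , drop = FALSE]
  lines <- vapply(seq_len(nrow(graph)), function(i) {
    paste(term_out(graph$subject[i], "uri"),
          term_out(graph$predicate[i], "uri"),
          term_out(graph$object[i], graph$object_type[i]),
          ".")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# one-term tokenizer for the emitted subset: <uri>, prefix:local, "literal"
parse_term <- function(token, prefixes) {
  if (startsWith(token, "<")) {
    list(value = substring(token, 2, nchar(token) - 1), type = "uri")
  } else if (startsWith(token, "\"")) {
    list(value = unescape_literal(substring(token, 2, nchar(token) - 1)),
         type = "literal")
  } else {
    m <- regmatches(token, regexec("^([A-Za-z][A-Za-z0-9]*):(.*)$", token))[[1]]
    if (length(m) == 0 || !m[2] %in% names(prefixes)) {
      stop("cannot parse RDF term: ", token, call. = FALSE)
    }
    list(value = paste0(prefixes[[m[2]]], m[3]), type = "uri")
  }
}

split_triple_line <- function(line) {
  # split into three terms + trailing dot, honoring quoted literals
  tokens <- character(0)
  i <- 1
  n <- nchar(line)
  while (i <= n && length(tokens) < 3) {
    ch <- substr(line, i, i)
    if (ch == " ") { i <- i + 1; next }
    if (ch == "<") {
      j <- regexpr(">", substring(line, i))[1] + i - 1
      tokens <- c(tokens, substr(line, i, j)); i <- j + 1
    } else if (ch == "\"") {
      j <- i + 1
      while (j <= n) {
        cj <- substr(line, j, j)
        if (cj == "\\") { j <- j + 2; next }
        if (cj == "\"") break
        j <- j + 1
      }
      tokens <- c(tokens, substr(line, i, j)); i <- j + 1
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ")) j <- j + 1
      tokens <- c(tokens, substr(line, i, j - 1)); i <- j
    }
  }
  tokens
}

#' Parse a Turtle or N-Triples file written by this package
#'
#' Covers the emitted subset: optional `@prefix` declarations, then one triple
#' per line.
#' @param path file to read.
#' @return Triple data frame.
#' @export
read_turtle <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  prefixes <- list()
  triples <- list()
  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, "@prefix")) {
      m <- regmatches(line, regexec("^@prefix +([A-Za-z][A-Za-z0-9]*): +<([^>]*)> *\\.$", line))[[1]]
      if (length(m) == 0) stop("bad @prefix line: ", line, call. = FALSE)
      prefixes[[m[2]]] <- m[3]
      next
    }
    tokens <- split_triple_line(line)
    if (length(tokens) != 3) stop("cannot parse triple line: ", line, call. = FALSE)
    s <- parse_term(tokens[1], prefixes)
    p <- parse_term(tokens[2], prefixes)
    o <- parse_term(tokens[3], prefixes)
    triples[[length(triples) + 1]] <- triple_df(s$value, p$value, o$value, o$type)
  }
  if (length(triples) == 0) return(triple_df())
  do.call(rbind, triples)
}
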