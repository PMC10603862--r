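#' @title Partitioned triple store
#'
#' @description The knowledge space is the framework's persistent memory: a
#' set of subject--predicate--object triples partitioned into four named
#' graphs — \code{services} (microservice descriptors), \code{contexts}
#' (task contexts), \code{policies} (recorded outcomes with rewards) and
#' \code{world} (reusable task-derived facts). Insertion is set-semantic:
#' adding a triple that is already present is a no-op.
#'
#' Internally each partition is a data frame with columns \code{s}, \code{p},
#' \code{o}, \code{o_kind}; \code{o_kind} is one of \code{iri},
#' \code{string}, \code{number}, \code{boolean}. Numeric literals are held in
#' a canonical 17-significant-digit decimal form so that serialisation round
#' trips are exact.
#'
#' @name knowledge_space
NULL

.canon_number <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
  sprintf("%.17g", as.numeric(x))
}

#' Construct a literal object for a triple
#'
#' Wraps a value so that [triple()] stores it as a typed literal rather than
#' an identifier. Kind is inferred from the R type: character gives a string
#' literal, numeric a number, logical a boolean.
#'
#' @param value Length-1 character, numeric or logical.
#' @return An object of class \code{sf_literal}.
#' @export
lit <- function(value) {
  stopifnot(length(value) == 1L, !is.na(value))
  kind <- if (is.character(value)) "string"
  else if (is.logical(value)) "boolean"
  else if (is.numeric(value)) "number"
  else stop("literal must be character, numeric or logical")
  structure(list(value = value, kind = kind), class = "sf_literal")
}

#' Construct a triple
#'
#' @param subject Non-empty identifier string.
#' @param predicate Non-empty identifier string.
#' @param object Identifier string, or a literal built with [lit()].
#' @return A one-row data frame with columns \code{s}, \code{p}, \code{o},
#'   \code{o_kind}.
#' @export
triple <- function(subject, predicate, object) {
  stopifnot(is.character(subject), length(subject) == 1L, nzchar(subject),
            is.character(predicate), length(predicate) == 1L, nzchar(predicate))
  if (inherits(object, "sf_literal")) {
    o_kind <- object$kind
    o <- switch(o_kind,
      string  = as.character(object$value),
      number  = .canon_number(object$value),
      boolean = if (isTRUE(object$value)) "true" else "false")
  } else {
    stopifnot(is.character(object), length(object) == 1L, nzchar(object))
    o <- object
    o_kind <- "iri"
  }
  data.frame(s = subject, p = predicate, o = o, o_kind = o_kind,
             stringsAsFactors = FALSE)
}

.empty_partition <- function() {
  data.frame(s = character(), p = character(), o = character(),
             o_kind = character(), stringsAsFactors = FALSE)
}

#' Create an empty knowledge space
#'
#' @return A \code{knowledge_space} with the four empty partitions
#'   \code{services}, \code{contexts}, \code{policies}, \code{world}.
#' @export
knowledge_space <- function() {
  parts <- lapply(PARTITIONS, function(p) .empty_partition())
  names(parts) <- PARTITIONS
  structure(list(partitions = parts), class = "knowledge_space")
}

.check_partition <- function(partition) {
  if (!(is.character(partition) && length(partition) == 1L &&
        partition %in% PARTITIONS)) {
    stop("unknown partition: ", partition, call. = FALSE)
  }
  partition
}

.triple_key <- function(df) {
  paste(df$s, df$p, df$o, df$o_kind, sep = "\r")
}

#' Add triples to a partition
#'
#' Set-semantic and monotone: duplicates are dropped, nothing is ever
#' removed.
#'
#' @param space A [knowledge_space()].
#' @param partition One of \code{services}, \code{contexts},
#'   \code{policies}, \code{world}.
#' @param triples A data frame of triples (rows as produced by [triple()]),
#'   or a list of such data frames.
#' @return The updated knowledge space.
#' @export
ks_add_triples <- function(space, partition, triples) {
  stopifnot(inherits(space, "knowledge_space"))
  .check_partition(partition)
  if (is.list(triples) && !is.data.frame(triples)) {
    triples <- do.call(rbind, triples)
  }
  if (is.null(triples) || nrow(triples) == 0L) return(space)
  stopifnot(all(c("s", "p", "o", "o_kind") %in% names(triples)))
  cur <- space$partitions[[partition]]
  new <- triples[!duplicated(.triple_key(triples)), , drop = FALSE]
  new <- new[!(.triple_key(new) %in% .triple_key(cur)), , drop = FALSE]
  space$partitions[[partition]] <- rbind(cur, new)
  rownames(space$partitions[[partition]]) <- NULL
  space
}

#' Number of triples in the space or one partition
#' @param space A knowledge space.
#' @param partition Optional partition name; default counts all.
#' @export
ks_size <- function(space, partition = NULL) {
  if (is.null(partition)) return(sum(vapply(space$partitions, nrow, 0L)))
  nrow(space$partitions[[.check_partition(partition)]])
}

#' Pattern-match triples
#'
#' Returns every triple unifying with the pattern; \code{NULL} in a position
#' is a wildcard. Results are sorted by subject, predicate, object so output
#' order is deterministic.
#'
#' @param space A knowledge space.
#' @param partition A partition name, or \code{"ALL"} to search every
#'   partition.
#' @param subject,predicate Identifier to match, or \code{NULL} (wildcard).
#' @param object Identifier, a [lit()] value, or \code{NULL} (wildcard).
#' @return Data frame of matching triples with a \code{partition} column.
#' @export
ks_match <- function(space, partition = "ALL", subject = NULL,
                     predicate = NULL, object = NULL) {
  stopifnot(inherits(space, "knowledge_space"))
  parts <- if (identical(partition, "ALL")) PARTITIONS
           else .check_partition(partition)
  o <- NULL; o_kind <- NULL
  if (!is.null(object)) {
    tr <- triple("x", "x", object)
    o <- tr$o; o_kind <- tr$o_kind
  }
  res <- lapply(parts, function(pn) {
    df <- space$partitions[[pn]]
    keep <- rep(TRUE, nrow(df))
    if (!is.null(subject))   keep <- keep & df$s == subject
    if (!is.null(predicate)) keep <- keep & df$p == predicate
    if (!is.null(o))         keep <- keep & df$o == o & df$o_kind == o_kind
    out <- df[keep, , drop = FALSE]
    if (nrow(out)) out$partition <- pn else out$partition <- character()
    out
  })
  res <- do.call(rbind, res)
  res <- res[order(res$s, res$p, res$o, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Test two knowledge spaces for equality
#'
#' Partition-wise set equality of triples (row order is immaterial).
#' @param a,b Knowledge spaces.
#' @export
ks_equal <- function(a, b) {
  all(vapply(PARTITIONS, function(pn) {
    setequal(.triple_key(a$partitions[[pn]]), .triple_key(b$partitions[[pn]]))
  }, TRUE))
}

# -- serialisation ------------------------------------------------------------
# Partition membership is encoded with the reserved predicate `inPartition`
# on a per-partition marker node; the statements that follow a marker belong
# to that partition. This keeps the output plain N-Triples / Turtle while
# remaining losslessly parseable by the paired reader.

.XSD_DOUBLE  <- "http://www.w3.org/2001/XMLSchema#double"
.XSD_BOOLEAN <- "http://www.w3.org/2001/XMLSchema#boolean"

# Percent-encode a local name so arbitrary identifier strings survive IRI
# syntax; alphanumerics and ._- pass through.
.enc_local <- function(x) {
  vapply(x, function(s) {
    bytes <- charToRaw(enc2utf8(s))
    chars <- rawToChar(bytes, multiple = TRUE)
    ok <- grepl("^[A-Za-z0-9._-]$", chars)
    paste0(ifelse(ok, chars, sprintf("%%%02X", as.integer(bytes))),
           collapse = "")
  }, "", USE.NAMES = FALSE)
}

.dec_local <- function(x) {
  vapply(x, function(s) utils::URLdecode(s), "", USE.NAMES = FALSE)
}

.esc_string <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

.unesc_string <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    res <- character(0)
    j <- 1L; n <- nchar(s)
    while (j <= n) {
      ch <- substr(s, j, j)
      if (ch == "\\" && j < n) {
        nx <- substr(s, j + 1L, j + 1L)
        res <- c(res, switch(nx, n = "\n", r = "\r", t = "\t",
                             "\\" = "\\", "\"" = "\"", nx))
        j <- j + 2L
      } else {
        res <- c(res, ch)
        j <- j + 1L
      }
    }
    out[[i]] <- paste0(res, collapse = "")
  }
  out
}

.fmt_iri <- function(local, dialect) {
  if (dialect == "turtle") paste0("sf:", .enc_local(local))
  else paste0("<", sf_namespace(), .enc_local(local), ">")
}

.fmt_object <- function(o, o_kind, dialect) {
  switch(o_kind,
    iri     = .fmt_iri(o, dialect),
    string  = paste0("\"", .esc_string(o), "\""),
    number  = paste0("\"", o, "\"^^<", .XSD_DOUBLE, ">"),
    boolean = paste0("\"", o, "\"^^<", .XSD_BOOLEAN, ">"))
}

#' Serialise a knowledge space
#'
#' @param space A knowledge space.
#' @param dialect \code{"ntriples"} (default) or \code{"turtle"}.
#' @return A single string; parseable by [ks_parse()].
#' @export
ks_serialize <- function(space, dialect = c("ntriples", "turtle")) {
  dialect <- match.arg(dialect)
  lines <- character(0)
  if (dialect == "turtle") {
    lines <- c(lines, paste0("@prefix sf: <", sf_namespace(), "> ."), "")
  }
  for (pn in PARTITIONS) {
    df <- space$partitions[[pn]]
    if (nrow(df) == 0L) next
    df <- df[order(df$s, df$p, df$o, method = "radix"), , drop = FALSE]
    marker <- paste(.fmt_iri(paste0("partition_", pn), dialect),
                    .fmt_iri("inPartition", dialect),
                    paste0("\"", pn, "\""), ".")
    stmts <- paste(.fmt_iri(df$s, dialect),
                   .fmt_iri(df$p, dialect),
                   mapply(.fmt_object, df$o, df$o_kind,
                          MoreArgs = list(dialect = dialect)),
                   ".")
    lines <- c(lines, marker, stmts)
  }
  paste0(paste(lines, collapse = "\n"),
         if (length(lines)) "\n" else "")
}

# Tokenise one statement line into subject, predicate, object; quotes and
# escapes respected. Returns NULL on malformed input.
.parse_line <- function(line, dialect) {
  s <- sub("\\s+$", "", sub("^\\s+", "", line))
  if (!grepl("\\.$", s)) return(NULL)
  s <- sub("\\s*\\.$", "", s)
  toks <- character(0)
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "<") {
      j <- regexpr(">", substr(s, i, n), fixed = TRUE)
      if (j < 0) return(NULL)
      toks <- c(toks, substr(s, i, i + j - 1L)); i <- i + j
    } else if (ch == "\"") {
      j <- i + 1L; closed <- FALSE
      while (j <= n) {
        cj <- substr(s, j, j)
        if (cj == "\\") { j <- j + 2L; next }
        if (cj == "\"") { closed <- TRUE; break }
        j <- j + 1L
      }
      if (!closed) return(NULL)
      # take optional ^^<datatype> suffix
      k <- j
      if (substr(s, j + 1L, j + 2L) == "^^") {
        m <- regexpr(">", substr(s, j + 3L, n), fixed = TRUE)
        if (m < 0) return(NULL)
        k <- j + 2L + m
      }
      toks <- c(toks, substr(s, i, k)); i <- k + 1L
    } else {
      j <- regexpr("[ \t]", substr(s, i, n))
      if (j < 0) { toks <- c(toks, substr(s, i, n)); i <- n + 1L }
      else { toks <- c(toks, substr(s, i, i + j - 2L)); i <- i + j - 1L }
    }
  }
  if (length(toks) != 3L) return(NULL)
  toks
}

.parse_term_iri <- function(tok) {
  ns <- sf_namespace()
  if (startsWith(tok, "<") && endsWith(tok, ">")) {
    iri <- substr(tok, 2L, nchar(tok) - 1L)
    if (!startsWith(iri, ns)) return(NULL)
    return(.dec_local(substring(iri, nchar(ns) + 1L)))
  }
  if (startsWith(tok, "sf:")) return(.dec_local(substring(tok, 4L)))
  NULL
}

.parse_object <- function(tok) {
  if (startsWith(tok, "\"")) {
    m <- regmatches(tok, regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^<([^>]*)>)?$',
                                 tok))[[1]]
    if (length(m) == 0L) return(NULL)
    raw <- .unesc_string(m[2]); dt <- m[3]
    if (is.na(dt) || dt == "") return(list(o = raw, o_kind = "string"))
    if (dt == .XSD_DOUBLE) {
      v <- suppressWarnings(as.numeric(raw))
      if (is.na(v)) return(NULL)
      return(list(o = .canon_number(v), o_kind = "number"))
    }
    if (dt == .XSD_BOOLEAN) {
      if (!raw %in% c("true", "false")) return(NULL)
      return(list(o = raw, o_kind = "boolean"))
    }
    return(NULL)
  }
  loc <- .parse_term_iri(tok)
  if (is.null(loc)) return(NULL)
  list(o = loc, o_kind = "iri")
}

#' Parse a serialised knowledge space
#'
#' Inverse of [ks_serialize()]: \code{ks_parse(ks_serialize(s, d), d)} equals
#' \code{s} for every valid space and both dialects.
#'
#' @param text Serialised text.
#' @param dialect \code{"ntriples"} or \code{"turtle"}.
#' @return A knowledge space.
#' @export
ks_parse <- function(text, dialect = c("ntriples", "turtle")) {
  dialect <- match.arg(dialect)
  space <- knowledge_space()
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  current <- NULL
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (grepl("^@prefix", line)) next
    toks <- .parse_line(line, dialect)
    if (is.null(toks)) stop("malformed statement at line ", i, call. = FALSE)
    s <- .parse_term_iri(toks[1]); p <- .parse_term_iri(toks[2])
    obj <- .parse_object(toks[3])
    if (is.null(s) || is.null(p) || is.null(obj)) {
      stop("malformed statement at line ", i, call. = FALSE)
    }
    if (p == "inPartition" && startsWith(s, "partition_")) {
      current <- obj$o
      if (!current %in% PARTITIONS) {
        stop("malformed statement at line ", i, ": unknown partition",
             call. = FALSE)
      }
      next
    }
    if (is.null(current)) {
      stop("malformed statement at line ", i,
           ": statement before any partition marker", call. = FALSE)
    }
    tr <- data.frame(s = s, p = p, o = obj$o, o_kind = obj$o_kind,
                     stringsAsFactors = FALSE)
    space <- ks_add_triples(space, current, tr)
  }
  space
}

#' @export
print.knowledge_space <- function(x, ...) {
  cat("<knowledge_space>", ks_size(x), "triples\n")
  for (pn in PARTITIONS) cat(sprintf("  %-9s %d\n", pn, ks_size(x, pn)))
  invisible(x)
}
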