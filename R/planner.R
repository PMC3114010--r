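#' Parse a SPARQL-subset query
#'
#' Supported: `PREFIX` declarations, `SELECT ?v ...`, `FROM <iri-or-path>`,
#' and a `WHERE { ... }` basic graph pattern of triple patterns (variables,
#' prefixed names, absolute IRIs, literals; `a` for `rdf:type`). Out-of-subset
#' keywords (`OPTIONAL`, `FILTER`, `UNION`, `GRAPH`) raise an
#' unsupported-feature error. Comments (`#`) run to end of line.
#'
#' @param text query text.
#' @return a `sparql_query`: list with `prefixes`, `select` (variable names),
#'   `from` (source IRIs/paths) and `pattern` (data.frame `s`, `p`, `o`,
#'   encoded terms with variables as `?name`).
#' @export
parse_query <- function(text) {
  text <- paste(text, collapse = "\n")
  for (bad in c("OPTIONAL", "FILTER", "UNION", "GRAPH ")) {
    if (grepl(bad, text, ignore.case = TRUE))
      stop("unsupported SPARQL feature: ", trimws(bad), call. = FALSE)
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("(^|\\s)#.*$", "\\1", lines)  # comments; '#' inside IRIs has no preceding space
  src <- paste(lines, collapse = "\n")

  prefixes <- list()
  pfx_re <- "(?i)PREFIX\\s+([A-Za-z][A-Za-z0-9_-]*)?:\\s*<?([^>\\s]+?)>?(?=\\s|$)"
  for (m in regmatches(src, gregexpr(pfx_re, src, perl = TRUE))[[1]]) {
    parts <- regmatches(m, regexec(pfx_re, m, perl = TRUE))[[1]]
    ns <- sub("\\.$", "", parts[3])  # a bare trailing dot is punctuation
    prefixes[[if (nzchar(parts[2])) parts[2] else ""]] <- ns
  }
  sel_m <- regmatches(src, regexec("(?i)select\\s+((\\?[A-Za-z0-9_]+\\s*)+)",
                                   src, perl = TRUE))[[1]]
  if (length(sel_m) == 0L) stop("query has no SELECT clause", call. = FALSE)
  select <- regmatches(sel_m[2], gregexpr("\\?[A-Za-z0-9_]+", sel_m[2]))[[1]]
  select <- substring(select, 2L)

  from <- character(0)
  from_re <- "(?i)FROM\\s*<?([^>\\s]+?)>?(?=\\s|$)"
  for (m in regmatches(src, gregexpr(from_re, src, perl = TRUE))[[1]]) {
    parts <- regmatches(m, regexec(from_re, m, perl = TRUE))[[1]]
    from <- c(from, sub("\\.$", "", parts[2]))
  }
  body_m <- regmatches(src, regexec("(?is)where\\s*\\{(.*)\\}", src, perl = TRUE))[[1]]
  if (length(body_m) == 0L) stop("query has no WHERE clause", call. = FALSE)
  pattern <- parse_bgp(body_m[2], prefixes)
  missing <- setdiff(select, pattern_variables(pattern))
  if (length(missing) > 0L)
    stop("select variable(s) not in pattern: ",
         paste0("?", missing, collapse = ", "), call. = FALSE)
  structure(list(prefixes = prefixes, select = select, from = from,
                 pattern = pattern), class = "sparql_query")
}

pattern_variables <- function(pattern) {
  terms <- c(pattern$s, pattern$p, pattern$o)
  unique(substring(terms[startsWith(terms, "?")], 2L))
}

parse_bgp <- function(body, prefixes) {
  stmts <- strsplit(body, "\\.\\s*(\n|$)|\\.\\s+", perl = TRUE)[[1]]
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]
  rows <- list()
  term_of <- function(tok) {
    if (startsWith(tok, "?")) return(tok)
    if (tok == "a") return(iri(paste0(NS$rdf, "type")))
    if (grepl("^<.*>$", tok)) return(tok)
    if (grepl("^\".*\"$", tok)) return(lit(substr(tok, 2L, nchar(tok) - 1L)))
    if (grepl("^-?[0-9]+$", tok)) return(lit(as.integer(tok), XSD$integer))
    if (grepl("^-?[0-9]*\\.[0-9]+$", tok)) return(lit(as.numeric(tok), XSD$double))
    m <- regmatches(tok, regexec("^([A-Za-z][A-Za-z0-9_-]*)?:([A-Za-z0-9_.-]+)$", tok))[[1]]
    if (length(m) == 3L) {
      ns <- prefixes[[if (nzchar(m[2])) m[2] else ""]]
      if (is.null(ns)) {
        dflt <- default_prefixes()
        if (m[2] %in% names(dflt)) ns <- dflt[[m[2]]]
        else stop("undeclared prefix in query: ", m[2], call. = FALSE)
      }
      return(iri(paste0(ns, m[3])))
    }
    stop("cannot parse query term: ", tok, call. = FALSE)
  }
  for (st in stmts) {
    toks <- strsplit(trimws(st), "\\s+")[[1]]
    # re-join quoted literals split on spaces
    joined <- character(0); buf <- NULL
    for (tk in toks) {
      if (!is.null(buf)) {
        buf <- paste(buf, tk)
        if (grepl("\"$", tk)) { joined <- c(joined, buf); buf <- NULL }
      } else if (grepl("^\"", tk) && !grepl("\"$", tk)) buf <- tk
      else joined <- c(joined, tk)
    }
    toks <- joined
    if (length(toks) != 3L)
      stop("triple pattern must have 3 terms: ", st, call. = FALSE)
    rows[[length(rows) + 1L]] <- vapply(toks, term_of, "")
  }
  out <- do.call(rbind, rows)
  data.frame(s = out[, 1], p = out[, 2], o = out[, 3], stringsAsFactors = FALSE)
}

#' Load the FROM sources of a query into one graph
#'
#' Sources are resolved offline: a readable local file path is parsed
#' directly (Turtle by extension `.ttl`/`.n3`, RDF/XML for `.rdf`/`.owl`/
#' `.xml`); the bundled service ontology IRI resolves to the packaged file.
#' Unresolvable remote IRIs are skipped with a warning (the ontology context
#' is supplied separately to [execute_query()]).
#'
#' @param query a `sparql_query`.
#' @param extra optional [rdf_graph()] merged in (e.g. the data graph).
#' @return an [rdf_graph()].
#' @export
load_sources <- function(query, extra = NULL) {
  g <- rdf_graph()
  for (src in query$from) {
    path <- src
    if (grepl("lipinskiserviceontology", src)) {
      path <- system.file("extdata", "lso.ttl", package = "semdesc",
                          mustWork = TRUE)
    }
    if (file.exists(path)) {
      txt <- readLines(path, warn = FALSE)
      g2 <- if (grepl("\\.(rdf|owl|xml)$", path) &&
                grepl("<\\?xml|<rdf:RDF", paste(txt[1:min(3, length(txt))],
                                                collapse = ""))) {
        parse_rdfxml(paste(txt, collapse = "\n"))
      } else parse_turtle(txt)
      g <- rdf_union(g, g2)
    } else if (grepl("^https?://", src)) {
      warning("FROM source not resolvable offline, skipped: ", src,
              call. = FALSE)
    } else {
      stop("FROM source not found: ", src, call. = FALSE)
    }
  }
  if (!is.null(extra)) g <- rdf_union(g, extra)
  g
}

# requirements implied by a query pattern: which (property, attribute type)
# annotations must exist, including those inside defined-class expressions
pattern_requirements <- function(query, ctx) {
  v <- vocab()
  reqs <- list()
  add_req <- function(property, type) {
    reqs[[length(reqs) + 1L]] <<- list(property = property, type = type)
  }
  walk_expr <- function(e, via = v$has_attribute) {
    switch(e$kind,
           and = for (p in e$parts) walk_expr(p, via),
           some = {
             filler <- e$filler
             named_types <- if (filler$kind == "named") filler$iri
             else if (filler$kind == "and")
               vapply(Filter(function(x) x$kind == "named", filler$parts),
                      `[[`, "", "iri")
             else character(0)
             for (ty in named_types) add_req(e$property, ty)
             walk_expr(filler, e$property)
           },
           named = {
             def <- ctx$definitions[[e$iri]]
             if (!is.null(def)) walk_expr(def, via)
           },
           invisible(NULL))
  }
  rdf_type <- iri(v$rdf_type)
  for (k in seq_len(nrow(query$pattern))) {
    p <- query$pattern$p[k]; o <- query$pattern$o[k]
    if (startsWith(o, "?") || startsWith(o, "\"")) next
    if (p == rdf_type) {
      cls <- iri_value(o)
      def <- ctx$definitions[[cls]]
      if (!is.null(def)) walk_expr(def)
      else add_req(v$has_attribute, cls)  # plain attribute typing pattern
    }
  }
  # attribute-type patterns joined through a property pattern:
  # ?s <prop> ?attr . ?attr rdf:type <T>
  for (k in seq_len(nrow(query$pattern))) {
    p <- query$pattern$p[k]
    if (startsWith(p, "?") || p == rdf_type) next
    attr_var <- query$pattern$o[k]
    if (!startsWith(attr_var, "?")) next
    types <- query$pattern$o[query$pattern$s == attr_var &
                               query$pattern$p == rdf_type]
    for (ty in types[!startsWith(types, "?")])
      add_req(iri_value(p), iri_value(ty))
  }
  unique_reqs <- list()
  seen <- character(0)
  for (r in reqs) {
    key <- paste(r$property, r$type)
    if (!(key %in% seen)) { seen <- c(seen, key); unique_reqs[[length(unique_reqs) + 1L]] <- r }
  }
  unique_reqs
}

# does `node` already carry an attribute/part satisfying the requirement? a
# plain rdf:type assertion of the requested class also counts (typing
# patterns over undefined classes are requirements only when unasserted)
requirement_met <- function(g, node, req, ctx) {
  v <- vocab()
  if (rdf_contains(g, node, iri(v$rdf_type), iri(req$type))) return(TRUE)
  preds <- property_closure(req$property, ctx)
  objs <- rdf_match(g, s = node, p = paste0("<", preds, ">"))$o
  objs <- objs[!startsWith(objs, "\"")]
  any(vapply(objs, function(o)
    rdf_contains(g, o, iri(v$rdf_type), iri(req$type)), TRUE))
}

#' Plan the service invocations needed to answer a query
#'
#' Backward chaining over the registry: for every annotation requirement in
#' the query (explicit attribute-type patterns and those implied by defined
#' classes) that the data does not already satisfy for some molecule node,
#' the first registered service producing it is planned; if that service's
#' input class is not yet satisfied for the node, a producer for the missing
#' restriction (e.g. a format converter) is planned first. Each
#' (service, node) pair is planned at most once, so plans are acyclic and
#' deterministic.
#'
#' @param query a `sparql_query`.
#' @param data an [rdf_graph()] with the input molecules.
#' @param registry a `service_registry`.
#' @param ctx ontology context (defaults to the registry's).
#' @return a `service_plan`: list of steps `list(service =, nodes =,
#'   justification =)` in execution order.
#' @export
plan <- function(query, data, registry, ctx = registry$ctx) {
  v <- vocab()
  reqs <- pattern_requirements(query, ctx)
  steps <- list()
  planned <- character(0)   # "service|node" keys
  unsatisfiable <- character(0)

  # nodes that could be molecules: typed molecule, or instances of a
  # registered input class
  candidates <- Filter(function(nd) {
    rdf_contains(data, nd, iri(v$rdf_type), iri(v$molecule)) ||
      is_instance(data, nd, ce_named(v$smilesmolecule), ctx) ||
      is_instance(data, nd, ce_named(v$inchimolecule), ctx)
  }, rdf_nodes(data))

  add_step <- function(svc, node, justification) {
    key <- paste(svc$name, node, sep = "|")
    if (key %in% planned) return(invisible(NULL))
    planned <<- c(planned, key)
    steps[[length(steps) + 1L]] <<- list(service = svc$name, nodes = node,
                                         justification = justification)
  }

  # would `node` satisfy the class after the already-planned steps ran? we
  # approximate by tracking which produced types are pending per node
  pending <- new.env(parent = emptyenv())
  note_pending <- function(node, types) {
    cur <- pending[[node]] %||2% character(0)
    pending[[node]] <- unique(c(cur, types))
  }
  has_pending <- function(node, type) {
    type %in% (pending[[node]] %||2% character(0))
  }

  satisfy_requirement <- function(req, node, depth = 0L) {
    if (depth > 5L) return(FALSE)
    if (requirement_met(data, node, req, ctx) || has_pending(node, req$type))
      return(TRUE)
    producers <- find_services_producing(registry, req$property, req$type, ctx)
    for (svc in producers) {
      key <- paste(svc$name, node, sep = "|")
      if (key %in% planned) next
      ok <- TRUE
      if (!is_instance(data, node, ce_named(svc$input_class), ctx)) {
        # can another service make the node qualify? inspect the unmet
        # conjuncts of the input class
        gaps <- unmet_conjuncts(data, node, svc$input_class, ctx)
        if (length(gaps) == 0L) { ok <- FALSE }
        for (gap in gaps) {
          if (!satisfy_requirement(gap, node, depth + 1L)) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      add_step(svc, node, sprintf("produce %s via %s", local_name(req$type),
                                  local_name(req$property)))
      note_pending(node, svc$produced_types)
      return(TRUE)
    }
    FALSE
  }

  for (req in reqs) {
    for (node in candidates) {
      if (!satisfy_requirement(req, node))
        unsatisfiable <- unique(c(unsatisfiable,
                                  sprintf("%s via %s", local_name(req$type),
                                          local_name(req$property))))
    }
  }
  structure(list(steps = steps, unsatisfiable = unsatisfiable),
            class = "service_plan")
}

# conjuncts of a (defined) class not yet satisfied by `node`, expressed as
# annotation requirements where possible
unmet_conjuncts <- function(g, node, class_iri, ctx) {
  def <- ctx$definitions[[class_iri]]
  if (is.null(def)) return(list())
  conjs <- if (def$kind == "and") def$parts else list(def)
  gaps <- list()
  for (cj in conjs) {
    if (eval_expr(g, node, cj, ctx, active = character(0))) next
    if (cj$kind == "some") {
      filler <- cj$filler
      named <- if (filler$kind == "named") filler$iri
      else if (filler$kind == "and") {
        nm <- Filter(function(x) x$kind == "named", filler$parts)
        if (length(nm) > 0L) nm[[1]]$iri else NULL
      } else NULL
      if (!is.null(named)) {
        gaps[[length(gaps) + 1L]] <- list(property = cj$property, type = named)
        next
      }
    }
    if (cj$kind == "named") {
      sub <- unmet_conjuncts(g, node, cj$iri, ctx)
      if (length(sub) > 0L) { gaps <- c(gaps, sub); next }
    }
    return(list())  # a gap no service annotation can close
  }
  gaps
}

#' @export
print.service_plan <- function(x, ...) {
  if (length(x$steps) == 0L) {
    cat("<plan> empty (data already sufficient)\n")
  } else {
    cat("<plan>", length(x$steps), "step(s):\n")
    for (k in seq_along(x$steps))
      cat(sprintf("  %d. %s on %s  [%s]\n", k, x$steps[[k]]$service,
                  x$steps[[k]]$nodes, x$steps[[k]]$justification))
  }
  if (length(x$unsatisfiable) > 0L)
    cat("  unsatisfiable:", paste(x$unsatisfiable, collapse = "; "), "\n")
  invisible(x)
}

#' Execute a query: plan, invoke, evaluate
#'
#' Runs the plan's service invocations on the data graph, then evaluates the
#' basic graph pattern on the materialized result. `rdf:type` patterns whose
#' class is defined in the ontology are answered by [is_instance()]
#' (materialize-then-match), so a molecule classifies into e.g. a
#' drug-likeness class without an asserted type triple. Non-type predicate
#' patterns match through the declared sub/equivalent property closure.
#'
#' @param query a `sparql_query` (or query text).
#' @param data an [rdf_graph()].
#' @param registry a `service_registry`.
#' @param ctx ontology context (defaults to the registry's).
#' @return list with `bindings` (data.frame, one column per select variable),
#'   `graph` (the materialized graph) and `plan`.
#' @export
execute_query <- function(query, data, registry, ctx = registry$ctx) {
  if (is.character(query)) query <- parse_query(query)
  pl <- plan(query, data, registry, ctx)
  g <- data
  completed <- character(0)
  for (step in pl$steps) {
    g <- tryCatch(invoke(registry, step$service, g, ctx),
                  error = function(e) {
                    stop(sprintf("service '%s' failed mid-plan (completed: %s): %s",
                                 step$service,
                                 if (length(completed) > 0L)
                                   paste(completed, collapse = ", ") else "none",
                                 conditionMessage(e)), call. = FALSE)
                  })
    completed <- c(completed, step$service)
  }
  bindings <- evaluate_bgp(query, g, ctx)
  sel <- bindings[, query$select, drop = FALSE]
  sel <- unique(sel)
  rownames(sel) <- NULL
  list(bindings = sel, graph = g, plan = pl)
}

#' Evaluate a basic graph pattern over a graph
#'
#' @param query a `sparql_query`.
#' @param g an [rdf_graph()].
#' @param ctx ontology context for defined-class `rdf:type` patterns and
#'   property closures.
#' @return data.frame of bindings (encoded terms), one column per variable.
#' @export
evaluate_bgp <- function(query, g, ctx = ontology_context()) {
  v <- vocab()
  rdf_type <- iri(v$rdf_type)
  rows <- list(stats::setNames(list(), character(0)))  # one empty binding
  all_nodes <- rdf_nodes(g)
  for (k in seq_len(nrow(query$pattern))) {
    ps <- query$pattern$s[k]; pp <- query$pattern$p[k]; po <- query$pattern$o[k]
    new_rows <- list()
    for (binding in rows) {
      subst <- function(t) {
        if (startsWith(t, "?")) {
          nm <- substring(t, 2L)
          if (nm %in% names(binding)) binding[[nm]] else NULL
        } else t
      }
      s0 <- subst(ps); p0 <- subst(pp); o0 <- subst(po)
      defined_class <- !is.null(p0) && p0 == rdf_type && !is.null(o0) &&
        startsWith(o0, "<") && !is.null(ctx$definitions[[iri_value(o0)]])
      matches <- if (defined_class) {
        cand <- if (is.null(s0)) all_nodes else s0
        hit <- Filter(function(nd)
          is_instance(g, nd, ce_named(iri_value(o0)), ctx), cand)
        if (length(hit) == 0L) data.frame(s = character(0), p = character(0),
                                          o = character(0))
        else data.frame(s = hit, p = rdf_type, o = o0, stringsAsFactors = FALSE)
      } else {
        pv <- if (is.null(p0)) NULL
        else if (startsWith(p0, "<"))
          paste0("<", property_closure(iri_value(p0), ctx), ">")
        else p0
        rdf_match(g, s = s0, p = pv, o = o0)
      }
      if (nrow(matches) == 0L) next
      for (r in seq_len(nrow(matches))) {
        b2 <- binding
        if (startsWith(ps, "?")) b2[[substring(ps, 2L)]] <- matches$s[r]
        if (startsWith(pp, "?")) b2[[substring(pp, 2L)]] <- matches$p[r]
        if (startsWith(po, "?")) b2[[substring(po, 2L)]] <- matches$o[r]
        new_rows[[length(new_rows) + 1L]] <- b2
      }
    }
    rows <- new_rows
    if (length(rows) == 0L) break
  }
  vars <- pattern_variables(query$pattern)
  if (length(rows) == 0L)
    return(stats::setNames(data.frame(matrix(character(0), 0, length(vars)),
                                      stringsAsFactors = FALSE), vars))
  out <- do.call(rbind, lapply(rows, function(b) {
    data.frame(as.list(b[vars]), stringsAsFactors = FALSE, check.names = FALSE)
  }))
  unique(out)
}

#' Saturate a graph against a registry (planner oracle)
#'
#' Invokes every applicable service repeatedly until no invocation adds a
#' triple. Terminates because services are idempotent and the attribute
#' vocabulary is finite. Used as the completeness oracle for [plan()] /
#' [execute_query()].
#'
#' @param data an [rdf_graph()].
#' @param registry a `service_registry`.
#' @param ctx ontology context (defaults to the registry's).
#' @return the fixpoint [rdf_graph()].
#' @export
saturate <- function(data, registry, ctx = registry$ctx) {
  g <- data
  repeat {
    before <- rdf_size(g)
    for (svc in registry$services) {
      g2 <- tryCatch(invoke(registry, svc$name, g, ctx),
                     error = function(e) g)
      g <- g2
    }
    if (rdf_size(g) == before) break
  }
  g
}
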