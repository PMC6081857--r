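#' Construct a Gene Ontology DAG
#'
#' Terms are ontology identifiers; edges point child -> parent and carry the
#' Wang semantic-contribution weight of their relation type: 0.8 for `is_a`
#' and 0.6 for `part_of`. The graph must be acyclic and closed (every edge
#' endpoint is a known term).
#'
#' @param terms Character vector of term IDs.
#' @param edges Data frame with columns `child`, `parent`, `type`
#'   (`"is_a"` or `"part_of"`); a `weight` column is derived from `type`.
#' @param namespace Optional named character vector, term ID -> namespace.
#' @return An object of class `go_dag` with components `terms`, `edges`,
#'   `namespace` and a child -> parents adjacency list.
#' @export
go_dag <- function(terms, edges, namespace = NULL) {
  terms <- unique(as.character(terms))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    stopifnot(all(c("child", "parent", "type") %in% names(edges)))
    unknown <- setdiff(c(edges$child, edges$parent), terms)
    if (length(unknown))
      stop("dangling edge endpoint(s) not declared as terms: ",
           paste(unknown, collapse = ", "))
    if (!all(edges$type %in% c("is_a", "part_of")))
      stop("edge types must be is_a or part_of")
    edges$weight <- ifelse(edges$type == "is_a", 0.8, 0.6)
  } else {
    edges <- data.frame(child = character(), parent = character(),
                        type = character(), weight = numeric())
  }
  parents <- split(seq_len(nrow(edges)), factor(edges$child, levels = terms))
  dag <- structure(list(terms = terms, edges = edges, parents = parents,
                        namespace = namespace),
                   class = "go_dag")
  assert_acyclic(dag)
  dag
}

assert_acyclic <- function(dag) {
  # DFS colouring over child -> parent edges; grey on the stack means a cycle
  colour <- stats::setNames(integer(length(dag$terms)), dag$terms)
  dfs <- function(t) {
    colour[[t]] <<- 1L
    for (i in dag$parents[[t]]) {
      p <- dag$edges$parent[i]
      if (colour[[p]] == 1L)
        stop("cycle detected in ontology involving term ", p)
      if (colour[[p]] == 0L) dfs(p)
    }
    colour[[t]] <<- 2L
  }
  for (start in dag$terms) if (colour[[start]] == 0L) dfs(start)
  invisible(TRUE)
}

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas, keeping `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of` lines. Obsolete terms are excluded, along with any
#' edges that mention them. Other relationship types are ignored.
#'
#' @param path Path to an OBO file.
#' @return A [go_dag()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  terms <- character(); ns <- character()
  obsolete <- character()
  child <- character(); parent <- character(); type <- character()
  cur <- NULL; in_term <- FALSE
  flush_term <- function() NULL
  cur_id <- NA_character_; cur_ns <- NA_character_; cur_obs <- FALSE
  cur_parents <- list()
  commit <- function() {
    if (is.na(cur_id)) return()
    if (cur_obs) {
      obsolete <<- c(obsolete, cur_id)
    } else {
      terms <<- c(terms, cur_id)
      ns[cur_id] <<- cur_ns
      for (pp in cur_parents) {
        child <<- c(child, cur_id)
        parent <<- c(parent, pp[[1L]])
        type <<- c(type, pp[[2L]])
      }
    }
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)      # strip trailing comments
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      if (in_term) commit()
      in_term <- identical(ln, "[Term]")
      cur_id <- NA_character_; cur_ns <- NA_character_
      cur_obs <- FALSE; cur_parents <- list()
      next
    }
    if (!in_term) next
    if (grepl("^id:", ln)) cur_id <- trimws(sub("^id:", "", ln))
    else if (grepl("^namespace:", ln)) cur_ns <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_obsolete:\\s*true", ln)) cur_obs <- TRUE
    else if (grepl("^is_a:", ln))
      cur_parents <- c(cur_parents, list(list(trimws(sub("^is_a:", "", ln)), "is_a")))
    else if (grepl("^relationship:\\s*part_of", ln))
      cur_parents <- c(cur_parents,
                       list(list(trimws(sub("^relationship:\\s*part_of", "", ln)),
                                 "part_of")))
  }
  if (in_term) commit()
  keep <- !(parent %in% obsolete)
  dangling <- setdiff(parent[keep], terms)
  if (length(dangling))
    stop("dangling parent reference(s) in OBO file: ",
         paste(dangling, collapse = ", "))
  go_dag(terms,
         data.frame(child = child[keep], parent = parent[keep],
                    type = type[keep], stringsAsFactors = FALSE),
         namespace = ns)
}

#' Write a `go_dag` in OBO 1.2 format
#'
#' @param dag A [go_dag()].
#' @param path Output file path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$terms) {
    writeLines(c("[Term]", paste0("id: ", t)), con)
    if (!is.null(dag$namespace) && !is.na(dag$namespace[t]))
      writeLines(paste0("namespace: ", dag$namespace[t]), con)
    idx <- dag$parents[[t]]
    for (i in idx) {
      if (dag$edges$type[i] == "is_a")
        writeLines(paste0("is_a: ", dag$edges$parent[i]), con)
      else
        writeLines(paste0("relationship: part_of ", dag$edges$parent[i]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read gene -> GO-term annotations
#'
#' Supports GAF 2.x (column 3 = gene symbol, column 5 = GO ID, `!` comments)
#' and plain two-column TSV (gene, term). Terms absent from `dag` are skipped
#' with a warning count; genes left with no resolvable term are dropped.
#'
#' @param path Path to the annotation file.
#' @param dag A [go_dag()] used to resolve term IDs.
#' @param format `"tsv"` or `"gaf"`.
#' @return Named list, gene ID -> character vector of term IDs (class
#'   `gene_annotation`).
#' @export
read_annotations <- function(path, dag, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(trimws(lines))]
  skipped_lines <- 0L
  genes <- character(); terms <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (format == "gaf") {
      if (length(f) < 5L || !nzchar(f[3L]) || !nzchar(f[5L])) {
        skipped_lines <- skipped_lines + 1L; next
      }
      genes <- c(genes, f[3L]); terms <- c(terms, f[5L])
    } else {
      if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L])) {
        skipped_lines <- skipped_lines + 1L; next
      }
      genes <- c(genes, f[1L]); terms <- c(terms, f[2L])
    }
  }
  if (skipped_lines)
    warning(skipped_lines, " malformed annotation line(s) skipped")
  known <- terms %in% dag$terms
  if (any(!known))
    warning(sum(!known), " annotation(s) referencing unknown terms skipped")
  genes <- genes[known]; terms <- terms[known]
  ann <- lapply(split(terms, genes), unique)
  ann <- ann[lengths(ann) > 0L]
  if (length(ann) == 0L) stop("no usable gene annotations found in ", path)
  gene_annotation(ann, dag)
}

#' Construct a gene-annotation mapping
#'
#' @param mapping Named list, gene ID -> character vector of term IDs.
#' @param dag A [go_dag()]; every term must resolve in it.
#' @return The validated mapping with class `gene_annotation`.
#' @export
gene_annotation <- function(mapping, dag) {
  stopifnot(is.list(mapping), !is.null(names(mapping)))
  if (any(lengths(mapping) == 0L)) stop("genes with empty term sets must be excluded")
  unknown <- setdiff(unique(unlist(mapping)), dag$terms)
  if (length(unknown))
    stop("annotation term(s) not in the DAG: ", paste(unknown, collapse = ", "))
  structure(mapping, class = "gene_annotation")
}

#' Restrict annotations to one namespace
#'
#' @param ann A [gene_annotation()].
#' @param dag A [go_dag()] with per-term namespaces.
#' @param namespace Namespace to keep (default `"biological_process"`).
#' @return A filtered [gene_annotation()]; genes with no term left are dropped.
#' @export
filter_namespace <- function(ann, dag, namespace = "biological_process") {
  if (is.null(dag$namespace)) return(ann)
  keep_terms <- dag$terms[!is.na(dag$namespace[dag$terms]) &
                            dag$namespace[dag$terms] == namespace]
  out <- lapply(ann, function(ts) intersect(ts, keep_terms))
  out <- out[lengths(out) > 0L]
  if (length(out) == 0L) stop("no genes annotated in namespace ", namespace)
  structure(out, class = "gene_annotation")
}
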