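#' Read and write cohort tables as delimited text
#'
#' Cohorts are exchanged as UTF-8 comma-separated files with a header row.
#' On read, categorical columns are restored as factors with the declared
#' level order from the codebook.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @param codebook A codebook tibble (see [ir_codebook()]).
#' @return `write_cohort()`: `path`, invisibly. `read_cohort()`: a tibble.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, codebook = ir_codebook()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (i in seq_len(nrow(codebook))) {
    v <- codebook$name[i]
    if (codebook$role[i] %in% c("categorical", "outcome") && v %in% names(d))
      d[[v]] <- factor(d[[v]], levels = codebook$levels[[i]])
  }
  validate_cohort(tibble::as_tibble(d), codebook)
  tibble::as_tibble(d)
}

#' Export a DAG in DOT format
#'
#' @param dag A `bn_dag`.
#' @param path Output file.
#' @param strengths Optional `arc_strength` table; arc labels then carry the
#'   bootstrap adjacency strength.
#' @return `path`, invisibly.
#' @export
write_dag_dot <- function(dag, path, strengths = NULL) {
  lines <- c("digraph bn {", "  node [shape=ellipse];")
  lines <- c(lines, paste0("  \"", dag$nodes, "\";"))
  if (nrow(dag$arcs)) {
    lab <- rep("", nrow(dag$arcs))
    if (!is.null(strengths)) {
      for (k in seq_len(nrow(dag$arcs))) {
        pr <- sort(dag$arcs[k, ])
        hit <- strengths$from == pr[1] & strengths$to == pr[2]
        if (any(hit))
          lab[k] <- sprintf(" [label=\"%.2f\"]", strengths$strength[which(hit)[1]])
      }
    }
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;",
                              dag$arcs[, 1], dag$arcs[, 2], lab))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write arc lists as delimited text
#'
#' Arc-list files are comma-separated with columns `from`, `to` and
#' optionally `strength`, `direction`; they serve as whitelist/blacklist
#' inputs and as the textual export of bootstrap strengths.
#'
#' @param x A `bn_dag`, `arc_strength` table, or two-column matrix.
#' @param path File path.
#' @return `write_arc_list()`: `path`, invisibly. `read_arc_list()`: a
#'   tibble with at least `from` and `to`.
#' @export
write_arc_list <- function(x, path) {
  d <- if (inherits(x, "bn_dag")) tidy(x)
       else tibble::as_tibble(as.data.frame(x))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_arc_list
#' @export
read_arc_list <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Serialize a fitted network to structured text
#'
#' The YAML document records nodes, declared levels, arcs, the smoothing
#' constant, and every CPT as a list of rows (parent configuration plus the
#' probability of each node level), so a fitted network round-trips through
#' plain text.
#'
#' @param fbn A `bn_fit`.
#' @param path File path.
#' @return `write_bn()`: `path`, invisibly. `read_bn()`: a `bn_fit`.
#' @export
write_bn <- function(fbn, path) {
  doc <- list(
    nodes = as.list(fbn$dag$nodes),
    levels = lapply(fbn$levels, as.list),
    arcs = apply(fbn$dag$arcs, 1, function(a) list(from = a[1], to = a[2])),
    alpha = fbn$alpha,
    cpts = lapply(names(fbn$cpts), function(v) {
      m <- fbn$cpts[[v]]
      list(node = v, parents = as.list(attr(m, "parents")),
           probs = apply(unname(m), 1, as.list))
    })
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_bn
#' @export
read_bn <- function(path) {
  doc <- yaml::read_yaml(path)
  nodes <- unlist(doc$nodes)
  lv <- lapply(doc$levels, function(x) as.character(unlist(x)))
  arcs <- if (length(doc$arcs))
    do.call(rbind, lapply(doc$arcs, function(a) c(a$from, a$to)))
  else NULL
  dag <- bn_dag(nodes, arcs)
  cpts <- list()
  for (entry in doc$cpts) {
    v <- entry$node
    pa <- as.character(unlist(entry$parents))
    m <- do.call(rbind, lapply(entry$probs, function(r) as.numeric(unlist(r))))
    colnames(m) <- lv[[v]]
    attr(m, "parents") <- pa
    cpts[[v]] <- m
  }
  cpts <- cpts[nodes]
  structure(list(dag = dag, cpts = cpts, levels = lv[nodes],
                 nlev = setNames(lengths(lv[nodes]), nodes),
                 alpha = doc$alpha),
            class = "bn_fit", uniform_rows = NA_integer_)
}

#' Write an exclusion log as JSON lines
#'
#' @param log The tibble from [exclusion_log()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log)))
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE), con)
  invisible(path)
}
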