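# --- provenance --------------------------------------------------------------

#' Provenance header lines for output files
#'
#' Every file the package writes starts with `#`-prefixed lines recording the
#' tool version, the seed and a hash of the run configuration, so a result
#' can always be traced back to what produced it. The timestamp line can be
#' suppressed for byte-reproducible output.
#'
#' @param seed integer seed used for the run (or `NA`).
#' @param config optional list; a short hash of its serialized form is
#'   recorded.
#' @param timestamp include a timestamp line.
#' @return Character vector of header lines.
#' @export
provenance_header <- function(seed = NA, config = NULL, timestamp = TRUE) {
  h <- c(sprintf("# prmt %s", as.character(utils::packageVersion("prmt"))),
         sprintf("# seed: %s", ifelse(is.na(seed), "none", seed)))
  if (!is.null(config)) {
    ser <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
    h <- c(h, sprintf("# config-hash: %08x", strtoi_hash(ser)))
  }
  if (timestamp) h <- c(h, sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  h
}

# small stable string hash (polynomial rolling hash mod a Mersenne prime)
strtoi_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  h
}

# --- tabular readers ---------------------------------------------------------

read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

#' Read an enzyme-function count table
#'
#' Accepts the wide layout (rows = enzyme functions, first column
#' `enzyme_id`, remaining columns samples) or the long layout (columns
#' `sample`, `enzyme_id`, `count`), auto-detected from the header. Cells must
#' be non-negative integers; enzyme/sample combinations absent from a long
#' file are zero.
#'
#' @param path path to the TSV (UTF-8, `#` comment lines allowed).
#' @return Integer matrix of class `count_table`, rows = enzyme functions
#'   (lexicographic), columns = samples.
#' @export
read_count_table <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) < 2L) stop("count table has no data rows: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  parse_count <- function(s, where) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v) || v < 0 || v != floor(v)) {
      stop(sprintf("non-integer or negative count '%s' at %s", s, where))
    }
    as.integer(v)
  }
  if (setequal(header, c("sample", "enzyme_id", "count"))) {
    i_s <- match("sample", header); i_e <- match("enzyme_id", header)
    i_c <- match("count", header)
    sample <- vapply(parts, `[`, character(1), i_s)
    enzyme <- vapply(parts, `[`, character(1), i_e)
    count <- mapply(function(p, ln) parse_count(p[i_c], sprintf("line %d", ln)),
                    parts, seq_along(parts) + 1L)
    samples <- sort(unique(sample)); enzymes <- sort(unique(enzyme))
    X <- matrix(0L, length(enzymes), length(samples),
                dimnames = list(enzymes, samples))
    X[cbind(match(enzyme, enzymes), match(sample, samples))] <- count
  } else {
    if (header[1L] != "enzyme_id") {
      stop("wide count table must have first column 'enzyme_id' ",
           "(or use long columns sample/enzyme_id/count)")
    }
    samples <- header[-1L]
    enzymes <- vapply(parts, `[`, character(1), 1L)
    X <- matrix(0L, length(enzymes), length(samples),
                dimnames = list(enzymes, samples))
    for (i in seq_along(parts)) {
      for (j in seq_along(samples)) {
        X[i, j] <- parse_count(parts[[i]][j + 1L],
                               sprintf("row '%s', column '%s'", enzymes[i], samples[j]))
      }
    }
    X <- X[order(rownames(X)), , drop = FALSE]
  }
  structure(X, class = c("count_table", class(X)))
}

#' Write a count table (wide layout)
#' @param counts a `count_table` or integer matrix.
#' @param path output path.
#' @param header optional provenance lines.
#' @export
write_count_table <- function(counts, path, header = NULL) {
  X <- unclass(counts)
  lines <- c(header,
             paste(c("enzyme_id", colnames(X)), collapse = "\t"),
             paste(rownames(X), apply(X, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

PARAMETER_CLASSES <- c("environmental-metabolite", "taxon-abundance",
                       "subsystem-abundance")

#' Read an environmental parameter / taxon-abundance table
#'
#' Wide TSV: columns `parameter_id`, `class` and one column per sample.
#' `class` must be one of `environmental-metabolite`, `taxon-abundance`,
#' `subsystem-abundance`.
#'
#' @param path path to the TSV.
#' @return Numeric matrix of class `parameter_table` (rows = parameters,
#'   columns = samples) with attribute `parameter_class` (named vector).
#' @export
read_parameter_table <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) < 2L) stop("parameter table has no data rows: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!all(c("parameter_id", "class") %in% header)) {
    stop("parameter table must have 'parameter_id' and 'class' columns")
  }
  i_id <- match("parameter_id", header); i_cl <- match("class", header)
  sample_cols <- setdiff(seq_along(header), c(i_id, i_cl))
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), i_id)
  if (anyDuplicated(ids)) {
    stop("duplicated parameter id: ", ids[duplicated(ids)][1L])
  }
  cls <- vapply(parts, `[`, character(1), i_cl)
  bad <- setdiff(unique(cls), PARAMETER_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown parameter class '", bad[1L], "' (expected one of: ",
         paste(PARAMETER_CLASSES, collapse = ", "), ")")
  }
  X <- do.call(rbind, lapply(parts, function(p) as.numeric(p[sample_cols])))
  dimnames(X) <- list(ids, header[sample_cols])
  names(cls) <- ids
  structure(X, parameter_class = cls,
            class = c("parameter_table", class(X)))
}

#' Write a parameter table
#' @param params a `parameter_table`.
#' @param path output path.
#' @param header optional provenance lines.
#' @export
write_parameter_table <- function(params, path, header = NULL) {
  X <- unclass(params)
  cls <- attr(params, "parameter_class")
  lines <- c(header,
             paste(c("parameter_id", "class", colnames(X)), collapse = "\t"),
             paste(rownames(X), cls[rownames(X)],
                   apply(X, 1L, function(r) paste(format_num(r), collapse = "\t")),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write PRMT scores
#'
#' Rows = metabolites, columns = samples, plus an `emm_degree` column (how
#' many enzyme functions touch the metabolite) when the EMM is supplied —
#' scores are easier to interpret in the context of the wider network.
#'
#' @param prmt a `prmt_table`.
#' @param path output path.
#' @param emm optional `emm` matrix for the degree column.
#' @param header optional provenance lines.
#' @export
write_prmt_table <- function(prmt, path, emm = NULL, header = NULL) {
  X <- unclass(prmt)
  cols <- c("metabolite", colnames(X))
  body <- paste(rownames(X),
                apply(X, 1L, function(r) paste(format_num(r), collapse = "\t")),
                sep = "\t")
  if (!is.null(emm)) {
    deg <- emm_degree(emm)[rownames(X)]
    cols <- c(cols, "emm_degree")
    body <- paste(body, deg, sep = "\t")
  }
  writeLines(c(header, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Read PRMT scores written by [write_prmt_table()]
#' @param path path to the TSV.
#' @return Matrix of class `prmt_table` (degree column, if present, dropped).
#' @export
read_prmt_table <- function(path) {
  lines <- read_tsv_lines(path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  keep <- setdiff(seq_along(header)[-1L], which(header == "emm_degree"))
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  X <- do.call(rbind, lapply(parts, function(p) as.numeric(p[keep])))
  dimnames(X) <- list(vapply(parts, `[`, character(1), 1L), header[keep])
  structure(X, class = c("prmt_table", class(X)))
}

#' Write flagged correlations
#' @param flagged output of [classify_strong()].
#' @param path output path.
#' @param header optional provenance lines.
#' @export
write_correlations <- function(flagged, path, header = NULL) {
  body <- paste(flagged$id_a, flagged$id_b, format_num(flagged$pcc),
                format_num(flagged$percentile), flagged$strong, flagged$sign,
                sep = "\t")
  writeLines(c(header, "id_a\tid_b\tpcc\tpercentile\tstrong\tsign", body), path)
  invisible(path)
}

#' Read flagged correlations written by [write_correlations()]
#' @param path path to the TSV.
#' @return data.frame with the [classify_strong()] columns.
#' @export
read_correlations <- function(path) {
  lines <- read_tsv_lines(path)
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  data.frame(id_a = vapply(parts, `[`, character(1), 1L),
             id_b = vapply(parts, `[`, character(1), 2L),
             pcc = as.numeric(vapply(parts, `[`, character(1), 3L)),
             percentile = as.numeric(vapply(parts, `[`, character(1), 4L)),
             strong = as.logical(vapply(parts, `[`, character(1), 5L)),
             sign = vapply(parts, `[`, character(1), 6L),
             stringsAsFactors = FALSE)
}

# --- network export ----------------------------------------------------------

#' Export a network for Cytoscape
#'
#' SIF: one `source <TAB> interaction <TAB> target` line per edge, with the
#' interaction taken from the edge `interaction` attribute (`pos`/`neg` for
#' correlation networks, `enzyme:<EC>` for metabolic networks); a node
#' attribute sidecar TSV (`<path>.nodes.tsv`) carries node types. GraphML
#' keeps all node and edge attributes in one file.
#'
#' @param graph an igraph graph (see [as_igraph_network()],
#'   [build_correlation_network()]).
#' @param format `"sif"` or `"graphml"`.
#' @param path output path.
#' @param header optional provenance lines (`#` comments for SIF, an XML
#'   comment for GraphML).
#' @export
export_network <- function(graph, format = c("sif", "graphml"), path,
                           header = NULL) {
  format <- match.arg(format)
  if (format == "sif") {
    edges <- igraph::as_data_frame(graph, what = "edges")
    interaction <- if (nrow(edges) > 0L && "interaction" %in% names(edges)) {
      edges$interaction
    } else rep("edge", nrow(edges))
    lines <- c(header,
               if (nrow(edges) > 0L) paste(edges$from, interaction, edges$to, sep = "\t"))
    if (is.null(lines)) lines <- "# empty network"
    writeLines(lines, path)
    nodes <- igraph::as_data_frame(graph, what = "vertices")
    sidecar <- paste0(path, ".nodes.tsv")
    type <- if ("type" %in% names(nodes)) nodes$type else rep("node", nrow(nodes))
    writeLines(c(header, "node\ttype",
                 if (nrow(nodes) > 0L) paste(nodes$name, type, sep = "\t")),
               sidecar)
  } else {
    igraph::write_graph(graph, path, format = "graphml")
    if (!is.null(header)) {
      lines <- readLines(path, warn = FALSE)
      comment <- paste0("<!-- ", paste(sub("^# ?", "", header), collapse = "; "), " -->")
      writeLines(c(lines[1L], comment, lines[-1L]), path)
    }
  }
  invisible(path)
}

# --- configuration -----------------------------------------------------------

#' Read a YAML run configuration
#'
#' Recognized keys: `catalog`, `blacklist`, `counts`, `parameters`,
#' `output_dir`, `transform`, `reference_samples`, `iterations`, `seed`,
#' `sign_convention`, `pseudocount`, `pathways`. Referenced paths are checked
#' to exist at validation time.
#'
#' @param path YAML file.
#' @return Named list of class `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("catalog", "blacklist", "counts", "parameters", "pathways")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("config path '%s' for '%s' does not exist", p, key))
    }
  }
  structure(cfg, class = "run_config")
}
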