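# --- reaction_catalog constructor and accessors ------------------------------

#' Construct a reaction catalog
#'
#' A reaction catalog is the parsed, filtered set of enzyme reactions that
#' defines the possible transformations of the environmental metabolome. Each
#' reaction links one enzyme function (an EC-number label) to a non-empty set
#' of substrate and product metabolites; stoichiometric coefficients are never
#' stored, only metabolite identity matters for turnover prediction.
#'
#' @param reactions data.frame with columns `reaction_id`, `enzyme_id`,
#'   `reversible` (logical), and list-columns `substrates`, `products`,
#'   `pathways` (character vectors; `pathways` may be empty).
#' @return An object of class `reaction_catalog`.
#' @export
reaction_catalog <- function(reactions) {
  required <- c("reaction_id", "enzyme_id", "reversible",
                "substrates", "products", "pathways")
  missing_cols <- setdiff(required, names(reactions))
  if (length(missing_cols) > 0L) {
    stop("reaction table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  key <- paste(reactions$reaction_id, reactions$enzyme_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1L]
    stop(sprintf("duplicate reaction_id + enzyme_id pair '%s' + '%s' (row %d)",
                 reactions$reaction_id[dup], reactions$enzyme_id[dup], dup))
  }
  if (any(!nzchar(reactions$enzyme_id))) stop("empty enzyme_id")
  n_sub <- lengths(reactions$substrates)
  n_pro <- lengths(reactions$products)
  if (any(n_sub == 0L) || any(n_pro == 0L)) {
    stop("reaction with empty substrate or product set at row ",
         which(n_sub == 0L | n_pro == 0L)[1L])
  }
  rownames(reactions) <- NULL
  structure(list(reactions = reactions), class = "reaction_catalog")
}

empty_catalog <- function() {
  reactions <- data.frame(reaction_id = character(0), enzyme_id = character(0),
                          reversible = logical(0))
  reactions$substrates <- list()
  reactions$products <- list()
  reactions$pathways <- list()
  structure(list(reactions = reactions), class = "reaction_catalog")
}

#' Metabolite universe of a catalog
#'
#' All metabolite ids referenced as substrate or product of any reaction.
#' @param catalog a `reaction_catalog`.
#' @return Sorted character vector.
#' @export
metabolite_universe <- function(catalog) {
  stopifnot(inherits(catalog, "reaction_catalog"))
  sort(unique(c(unlist(catalog$reactions$substrates),
                unlist(catalog$reactions$products))))
}

#' Enzyme-function universe of a catalog
#'
#' @param catalog a `reaction_catalog`.
#' @return Sorted character vector of unique enzyme-function (EC) labels.
#' @export
enzyme_universe <- function(catalog) {
  stopifnot(inherits(catalog, "reaction_catalog"))
  sort(unique(catalog$reactions$enzyme_id))
}

#' @export
print.reaction_catalog <- function(x, ...) {
  r <- x$reactions
  cat(sprintf("reaction_catalog: %d reactions (%d reversible), %d enzyme functions, %d metabolites\n",
              nrow(r), sum(r$reversible), length(unique(r$enzyme_id)),
              length(metabolite_universe(x))))
  invisible(x)
}

#' @export
length.reaction_catalog <- function(x) nrow(x$reactions)

# --- parsing -----------------------------------------------------------------

# strips a leading stoichiometric coefficient ("2 C00001", "n C00404",
# "(n+1) C00404") from one equation-side token; identity only is retained.
strip_coefficient <- function(token) {
  token <- trimws(token)
  stripped <- sub("^\\(?[0-9n+-]+\\)?[ ]+", "", token)
  out <- token
  keep <- nzchar(stripped)
  out[keep] <- stripped[keep]
  out
}

split_field <- function(field) {
  parts <- strsplit(field, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  unique(strip_coefficient(parts))
}

#' Parse a reaction table
#'
#' Reads a reaction catalog from either the generic tab-separated format or a
#' KEGG-REACTION-style flat file. In the generic format each row is one
#' (reaction, enzyme function) pair with columns `reaction_id`, `enzyme_id`,
#' `direction` (`"=>"` irreversible, `"<=>"` reversible), `substrates` and
#' `products` (semicolon-separated metabolite ids, optional leading
#' stoichiometric coefficients are discarded) and optional `pathway_ids`.
#' In the flat-file dialect, records are separated by `///` and only the
#' ENTRY, ENZYME, EQUATION and PATHWAY fields are consumed; a record listing
#' several EC numbers yields one reaction per EC number, and records without
#' an EC number are dropped (the metagenome counts are EC-labelled, so such
#' reactions can never receive abundance).
#'
#' @param path path to the reaction file.
#' @param dialect `"generic-tsv"` or `"kegg-flatfile"`.
#' @return A [reaction_catalog()].
#' @export
read_reaction_table <- function(path, dialect = c("generic-tsv", "kegg-flatfile")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "generic-tsv") parse_generic_tsv(lines) else parse_kegg_flatfile(lines)
}

parse_generic_tsv <- function(lines) {
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("empty reaction table; returning empty catalog")
    return(empty_catalog())
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  required <- c("reaction_id", "enzyme_id", "direction", "substrates", "products")
  if (!all(required %in% header)) {
    stop("reaction table header must contain: ", paste(required, collapse = ", "))
  }
  has_pathways <- "pathway_ids" %in% header
  body <- lines[-1L]
  body_no <- line_no[-1L]
  if (length(body) == 0L) {
    warning("reaction table has a header but no rows; returning empty catalog")
    return(empty_catalog())
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  get <- function(row, col) {
    i <- match(col, header)
    if (i > length(row)) "" else trimws(row[i])
  }
  n <- length(fields)
  reaction_id <- character(n); enzyme_id <- character(n); reversible <- logical(n)
  substrates <- vector("list", n); products <- vector("list", n)
  pathways <- vector("list", n)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    row <- fields[[i]]
    reaction_id[i] <- get(row, "reaction_id")
    enzyme_id[i] <- get(row, "enzyme_id")
    dir_tok <- get(row, "direction")
    if (dir_tok == "<=>") reversible[i] <- TRUE
    else if (dir_tok == "=>") reversible[i] <- FALSE
    else stop(sprintf("unknown direction token '%s' at line %d", dir_tok, body_no[i]))
    substrates[[i]] <- split_field(get(row, "substrates"))
    products[[i]] <- split_field(get(row, "products"))
    if (length(substrates[[i]]) == 0L || length(products[[i]]) == 0L) {
      stop(sprintf("empty substrate or product field at line %d", body_no[i]))
    }
    pathways[[i]] <- if (has_pathways) split_field(get(row, "pathway_ids")) else character(0)
    key <- paste(reaction_id[i], enzyme_id[i], sep = "\r")
    if (!is.null(seen[[key]])) {
      stop(sprintf("duplicate reaction_id + enzyme_id pair '%s' + '%s' at line %d",
                   reaction_id[i], enzyme_id[i], body_no[i]))
    }
    seen[[key]] <- TRUE
  }
  reactions <- data.frame(reaction_id = reaction_id, enzyme_id = enzyme_id,
                          reversible = reversible)
  reactions$substrates <- substrates
  reactions$products <- products
  reactions$pathways <- pathways
  reaction_catalog(reactions)
}

parse_kegg_equation <- function(eq) {
  reversible <- grepl("<=>", eq, fixed = TRUE)
  sides <- if (reversible) strsplit(eq, "<=>", fixed = TRUE)[[1L]]
           else strsplit(eq, "=>", fixed = TRUE)[[1L]]
  if (length(sides) != 2L) stop("malformed EQUATION line: ", eq)
  parse_side <- function(s) {
    toks <- trimws(strsplit(s, "+", fixed = TRUE)[[1L]])
    toks <- toks[nzchar(toks)]
    unique(strip_coefficient(toks))
  }
  list(substrates = parse_side(sides[1L]), products = parse_side(sides[2L]),
       reversible = reversible)
}

parse_kegg_flatfile <- function(lines) {
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    warning("empty reaction file; returning empty catalog")
    return(empty_catalog())
  }
  rec_id <- cumsum(grepl("^///", lines)) + 1L
  rec_id[grepl("^///", lines)] <- NA_integer_
  rows <- list()
  n_no_ec <- 0L
  for (rec in split(lines, rec_id)) {
    # field continuation: lines starting with whitespace extend the current field
    fields <- list()
    current <- NULL
    for (ln in rec) {
      if (!nzchar(trimws(ln))) next
      if (grepl("^\\S", ln)) {
        current <- sub("\\s.*$", "", ln)
        fields[[current]] <- c(fields[[current]], trimws(sub("^\\S+\\s*", "", ln)))
      } else if (!is.null(current)) {
        fields[[current]] <- c(fields[[current]], trimws(ln))
      }
    }
    if (is.null(fields$ENTRY)) next
    entry <- strsplit(fields$ENTRY[1L], "\\s+")[[1L]][1L]
    ecs <- unlist(strsplit(fields$ENZYME %||% character(0), "\\s+"))
    ecs <- ecs[nzchar(ecs)]
    if (length(ecs) == 0L) { n_no_ec <- n_no_ec + 1L; next }
    if (is.null(fields$EQUATION)) next
    eq <- parse_kegg_equation(paste(fields$EQUATION, collapse = " "))
    pw <- vapply(fields$PATHWAY %||% character(0),
                 function(p) strsplit(p, "\\s+")[[1L]][1L], character(1))
    pw <- unname(pw[nzchar(pw)])
    for (ec in ecs) {
      rows[[length(rows) + 1L]] <- list(reaction_id = entry, enzyme_id = ec,
                                        reversible = eq$reversible,
                                        substrates = eq$substrates,
                                        products = eq$products,
                                        pathways = pw)
    }
  }
  if (n_no_ec > 0L) {
    message(n_no_ec, " reaction record(s) without an EC number dropped")
  }
  if (length(rows) == 0L) {
    warning("no usable reaction records; returning empty catalog")
    return(empty_catalog())
  }
  reactions <- data.frame(
    reaction_id = vapply(rows, `[[`, character(1), "reaction_id"),
    enzyme_id = vapply(rows, `[[`, character(1), "enzyme_id"),
    reversible = vapply(rows, `[[`, logical(1), "reversible"))
  reactions$substrates <- lapply(rows, `[[`, "substrates")
  reactions$products <- lapply(rows, `[[`, "products")
  reactions$pathways <- lapply(rows, `[[`, "pathways")
  reaction_catalog(reactions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a catalog in the generic tab-separated format
#'
#' Inverse of [read_reaction_table()] with `dialect = "generic-tsv"`:
#' re-parsing the written file yields an identical catalog.
#'
#' @param catalog a `reaction_catalog`.
#' @param path output path.
#' @param header optional character vector of `#`-prefixed provenance lines.
#' @export
write_reaction_table <- function(catalog, path, header = NULL) {
  stopifnot(inherits(catalog, "reaction_catalog"))
  r <- catalog$reactions
  join <- function(xs) vapply(xs, paste, character(1), collapse = ";")
  lines <- c(header,
             paste("reaction_id", "enzyme_id", "direction", "substrates",
                   "products", "pathway_ids", sep = "\t"),
             paste(r$reaction_id, r$enzyme_id,
                   ifelse(r$reversible, "<=>", "=>"),
                   join(r$substrates), join(r$products), join(r$pathways),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# --- filtering ---------------------------------------------------------------

#' Restrict a catalog to reactions in allowed pathways
#'
#' Keeps reactions whose pathway annotation intersects `allowed` (for the
#' original study: the KEGG 'Metabolism' maps, excluding disease/drug maps).
#' Reactions carrying no pathway annotation are dropped and counted in a
#' message.
#'
#' @param catalog a `reaction_catalog`.
#' @param allowed non-empty character vector of pathway labels.
#' @return Filtered `reaction_catalog` (possibly empty, with a warning).
#' @export
filter_by_pathways <- function(catalog, allowed) {
  stopifnot(inherits(catalog, "reaction_catalog"))
  if (length(allowed) == 0L) stop("'allowed' pathway set must be non-empty")
  r <- catalog$reactions
  untagged <- lengths(r$pathways) == 0L
  keep <- vapply(r$pathways, function(p) any(p %in% allowed), logical(1))
  if (any(untagged)) {
    message(sum(untagged), " reaction(s) without pathway annotation dropped")
  }
  out <- r[keep & !untagged, , drop = FALSE]
  if (nrow(out) == 0L) warning("pathway filter removed every reaction")
  rownames(out) <- NULL
  structure(list(reactions = out), class = "reaction_catalog")
}

#' Remove currency metabolites from a catalog
#'
#' Deletes blacklisted metabolite ids (water, di-/tri-phosphonucleotides,
#' ubiquitous cofactors and the like) from every substrate and product set.
#' A reaction whose substrate or product side becomes empty is removed
#' entirely and counted in a message. Idempotent, and commutes with
#' [filter_by_pathways()].
#'
#' @param catalog a `reaction_catalog`.
#' @param blacklist character vector of metabolite ids (may be empty).
#' @return Filtered `reaction_catalog`.
#' @export
apply_metabolite_blacklist <- function(catalog, blacklist) {
  stopifnot(inherits(catalog, "reaction_catalog"))
  if (length(blacklist) == 0L) return(catalog)
  r <- catalog$reactions
  r$substrates <- lapply(r$substrates, setdiff, blacklist)
  r$products <- lapply(r$products, setdiff, blacklist)
  emptied <- lengths(r$substrates) == 0L | lengths(r$products) == 0L
  if (any(emptied)) {
    message(sum(emptied),
            " reaction(s) removed: one side fully blacklisted")
  }
  out <- r[!emptied, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(reactions = out), class = "reaction_catalog")
}

#' Read a metabolite blacklist file
#'
#' One metabolite id per line; `#` comments and blank lines ignored.
#' @param path path to the blacklist file.
#' @return Character vector of metabolite ids.
#' @export
read_blacklist <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("\\s.*$", "", lines)  # allow trailing description column
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Default currency-metabolite blacklist
#'
#' KEGG compound ids for water, the di- and tri-phosphonucleotides, the
#' NAD(P)(H)/FAD(H2) redox carriers, coenzyme A and the free proton. These
#' compounds appear in so many reactions that they connect otherwise unrelated
#' pathways and carry no turnover signal of their own. Orthophosphate and
#' pyrophosphate are deliberately absent: free phosphate is itself an
#' environmental analyte of interest.
#'
#' @return Character vector of KEGG compound ids.
#' @export
default_blacklist <- function() {
  read_blacklist(system.file("extdata", "default_blacklist.txt",
                             package = "prmt", mustWork = TRUE))
}

# --- direction expansion -----------------------------------------------------

#' Expand reactions into directed reactions
#'
#' An irreversible reaction yields one directed reaction (consumed =
#' substrates, produced = products); a reversible one yields its forward
#' direction immediately followed by its mirror image, so the output holds
#' exactly `nrow(catalog) + n_reversible` rows in catalog order.
#'
#' @param catalog a filtered `reaction_catalog`.
#' @return data.frame of class `directed_reactions` with columns
#'   `reaction_id`, `enzyme_id`, `direction` and list-columns `consumed`,
#'   `produced`.
#' @export
expand_directions <- function(catalog) {
  stopifnot(inherits(catalog, "reaction_catalog"))
  r <- catalog$reactions
  if (nrow(r) == 0L) {
    out <- data.frame(reaction_id = character(0), enzyme_id = character(0),
                      direction = character(0))
    out$consumed <- list(); out$produced <- list()
    class(out) <- c("directed_reactions", "data.frame")
    return(out)
  }
  idx <- rep(seq_len(nrow(r)), times = 1L + r$reversible)
  is_rev_copy <- unlist(lapply(seq_len(nrow(r)), function(i) {
    if (r$reversible[i]) c(FALSE, TRUE) else FALSE
  }))
  out <- data.frame(reaction_id = r$reaction_id[idx],
                    enzyme_id = r$enzyme_id[idx],
                    direction = ifelse(is_rev_copy, "reverse", "forward"))
  consumed <- r$substrates[idx]
  produced <- r$products[idx]
  consumed[is_rev_copy] <- r$products[idx][is_rev_copy]
  produced[is_rev_copy] <- r$substrates[idx][is_rev_copy]
  out$consumed <- consumed
  out$produced <- produced
  class(out) <- c("directed_reactions", "data.frame")
  out
}
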