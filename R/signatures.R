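#' Construct a gene signature
#'
#' A gene signature is a named, ordered set of unique gene symbols used for
#' mean-expression scoring (e.g. the T cell-inflamed signature or the 12-gene
#' p38 activation signature).
#'
#' @param name Single non-empty character label.
#' @param genes Character vector of unique, non-empty gene symbols without
#'   whitespace.
#' @return An object of class `gene_signature`: a list with elements `name`
#'   and `genes`.
#' @examples
#' gene_signature("MYSIG", c("TP53", "MYC"))
#' @export
gene_signature <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!nzchar(name)) stop("signature name must be non-empty", call. = FALSE)
  genes <- as.character(genes)
  if (length(genes) == 0L) {
    stop("signature '", name, "' has no genes", call. = FALSE)
  }
  if (any(!nzchar(genes)) || any(grepl("\\s", genes))) {
    stop("gene symbols must be non-empty and contain no whitespace",
         call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols in signature '", name, "'", call. = FALSE)
  }
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  cat(" ", paste(utils::head(x$genes, 10), collapse = ", "),
      if (length(x$genes) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Construct a directional pathway definition
#'
#' A pathway is identified by its upstream regulator (e.g. `MAPK14`, `CTNNB1`)
#' and carries its downstream target genes, each with the direction of
#' expression change expected under pathway activation.
#'
#' @param regulator Pathway / regulator label.
#' @param targets Character vector of unique target gene symbols.
#' @param directions Character vector, one of `"up"` or `"down"` per target.
#'   Recycled if length 1. Default all `"up"`.
#' @param source Free-text provenance note.
#' @return An object of class `pathway_def`: a list with `regulator`,
#'   `targets` (a tibble with columns `gene`, `direction`) and `source`.
#' @examples
#' pathway_definition("P38", c("VEGFA", "IL1A", "GADD45A"),
#'                    c("up", "up", "down"))
#' @export
pathway_definition <- function(regulator, targets,
                               directions = "up", source = "") {
  stopifnot(is.character(regulator), length(regulator) == 1L, nzchar(regulator))
  targets <- as.character(targets)
  if (length(targets) == 0L) {
    stop("pathway '", regulator, "' must have at least one target",
         call. = FALSE)
  }
  if (anyDuplicated(targets)) {
    stop("duplicate target symbols in pathway '", regulator, "'",
         call. = FALSE)
  }
  if (length(directions) == 1L) directions <- rep(directions, length(targets))
  if (length(directions) != length(targets)) {
    stop("directions must match targets in length", call. = FALSE)
  }
  bad <- setdiff(unique(directions), c("up", "down"))
  if (length(bad)) {
    stop("invalid direction token(s): ", paste(bad, collapse = ", "),
         " (allowed: 'up', 'down')", call. = FALSE)
  }
  structure(
    list(regulator = regulator,
         targets = tibble::tibble(gene = targets, direction = directions),
         source = source),
    class = "pathway_def"
  )
}

#' @export
print.pathway_def <- function(x, ...) {
  n_dn <- sum(x$targets$direction == "down")
  cat("<pathway_def> ", x$regulator, ": ", nrow(x$targets), " targets (",
      nrow(x$targets) - n_dn, " up, ", n_dn, " down)\n", sep = "")
  invisible(x)
}

# signed weights (+1 up / -1 down) for a pathway's targets, named by gene
target_signs <- function(pw) {
  stats::setNames(ifelse(pw$targets$direction == "down", -1, 1),
                  pw$targets$gene)
}

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sub("\r$", "", lines)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT layout: one signature per line, tab-separated fields
#' `name`, `description`, then gene symbols. Duplicate genes within a line are
#' collapsed with a warning; a line with fewer than three fields is an error.
#'
#' @param path Path to a GMT file (UTF-8; Unix or Windows line endings).
#' @return A named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  sigs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, " in ", path,
           ": expected at least 3 tab-separated fields", call. = FALSE)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) collapsed in signature '", fields[[1]],
              "' (line ", i, ")", call. = FALSE)
      genes <- unique(genes)
    }
    gene_signature(fields[[1]], genes)
  })
  stats::setNames(sigs, vapply(sigs, `[[`, "", "name"))
}

#' Write gene signatures to a GMT file
#'
#' @param signatures A list of [gene_signature()] objects (or a single one).
#' @param path Output path.
#' @param description Description field written as the second column.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path, description = "na") {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- vapply(signatures, function(s) {
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read directional pathway definitions from a GMT-dialect file
#'
#' Same layout as GMT, but each gene token may carry an `"|up"` or `"|down"`
#' suffix encoding the expected direction of expression change under pathway
#' activation; an unsuffixed token defaults to `"up"`. Any other suffix is a
#' parse error.
#'
#' @param path Path to the directional GMT file.
#' @return A named list of [pathway_definition()] objects.
#' @export
read_directional_gmt <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  pws <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("malformed directional GMT line ", i, " in ", path,
           ": expected at least 3 tab-separated fields", call. = FALSE)
    }
    tokens <- fields[-(1:2)]
    tokens <- tokens[nzchar(tokens)]
    parts <- strsplit(tokens, "|", fixed = TRUE)
    genes <- vapply(parts, `[[`, "", 1L)
    dirs <- vapply(parts, function(p) {
      if (length(p) == 1L) return("up")
      if (length(p) == 2L && p[[2]] %in% c("up", "down")) return(p[[2]])
      stop("invalid direction token '", paste(p, collapse = "|"),
           "' on line ", i, " in ", path, call. = FALSE)
    }, character(1))
    if (anyDuplicated(genes)) {
      warning("duplicate target(s) collapsed in pathway '", fields[[1]],
              "' (line ", i, ")", call. = FALSE)
      keep <- !duplicated(genes)
      genes <- genes[keep]
      dirs <- dirs[keep]
    }
    pathway_definition(fields[[1]], genes, dirs, source = fields[[2]])
  })
  stats::setNames(pws, vapply(pws, `[[`, "", "regulator"))
}

#' Write directional pathway definitions to a GMT-dialect file
#'
#' @param pathways A list of [pathway_definition()] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_directional_gmt <- function(pathways, path) {
  if (inherits(pathways, "pathway_def")) pathways <- list(pathways)
  lines <- vapply(pathways, function(pw) {
    src <- if (nzchar(pw$source)) pw$source else "na"
    tokens <- paste0(pw$targets$gene, "|", pw$targets$direction)
    paste(c(pw$regulator, src, tokens), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' The 12-gene p38 activation signature
#'
#' The packaged 12-gene signature of p38/MAPK pathway activation derived from
#' HPV-negative head and neck squamous cell carcinoma, used for per-tumor
#' p38 activation scoring (see [p38_score_tumors()]).
#'
#' @return A [gene_signature()] with the 12 gene symbols, in their canonical
#'   order. The result is identical on every call.
#' @examples
#' p38_signature()
#' @export
p38_signature <- function() {
  gene_signature("P38_ACTIVATION", c(
    "ARG2", "CD55", "CYP4F3", "FST", "GCLC", "IL1A",
    "MIF", "PLA2G4A", "PTGS2", "S100A12", "SLC6A2", "VEGFA"
  ))
}
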