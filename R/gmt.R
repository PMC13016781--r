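#' Gene-set collection container
#'
#' Lightweight container for a named collection of gene sets, as parsed from
#' or written to GMT files.
#'
#' @param sets Named list of character vectors (member gene ids); names must
#'   be unique and members non-empty.
#' @param descriptions Optional named character vector of set descriptions
#'   (defaults to empty strings).
#' @param source Free-text label for provenance.
#' @return Object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL,
                                source = "unspecified") {
  stopifnot(is.list(sets))
  if (length(sets) > 0) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      stop("set names must be present and unique")
    }
    if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  }
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 source = source),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (source: %s)\n",
              length(x$sets), x$source))
  if (length(x$sets) > 0) {
    cat(sprintf("  set sizes: %d-%d genes\n",
                min(lengths(x$sets)), max(lengths(x$sets))))
  }
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT dialect: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Lines with fewer than
#' three fields raise an error naming the line number; duplicate set names
#' are an error; duplicate members within a set are deduplicated with a
#' warning.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(gene_set_collection(list(), source = basename(path)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields",
                 bad[1]))
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1])
  }
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate members in set '%s' deduplicated", f[1]))
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  gene_set_collection(sets, setNames(desc, nm), source = basename(path))
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
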