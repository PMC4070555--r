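#' Gene-set collections
#'
#' A `gene_set_collection` holds named gene sets together with light
#' per-set metadata: a category (`"TFBS"`, `"GO_BP"`, `"GO_CC"`, `"GO_MF"`,
#' `"KEGG"` or `"OTHER"`), an optional transcription-factor label for TFBS
#' sets, and a free-text description. Gene symbols are matched
#' case-insensitively and stored upper-cased; duplicate symbols within a
#' set are collapsed.
#'
#' @param sets Named list of character vectors of gene symbols. Names must
#'   be unique and every set non-empty.
#' @param category Character vector (length 1 or `length(sets)`) of set
#'   categories; one of `"TFBS"`, `"GO_BP"`, `"GO_CC"`, `"GO_MF"`,
#'   `"KEGG"`, `"OTHER"`.
#' @param tf_label Optional character vector (length 1 or `length(sets)`)
#'   naming the transcription factor a TFBS set belongs to; `NA` otherwise.
#' @param description Character vector of free-text descriptions.
#'
#' @return An object of class `gene_set_collection`: a list with elements
#'   `sets` (named list of upper-cased, deduplicated gene vectors) and
#'   `info` (data frame with columns `name`, `category`, `tf_label`,
#'   `description`).
#' @export
#' @examples
#' gs <- gene_set_collection(
#'   list(SETA = c("tp53", "MDM2"), SETB = c("CDK1", "CCNB1", "TP53")),
#'   category = "OTHER"
#' )
#' set_sizes(gs)
gene_set_collection <- function(sets, category = "OTHER", tf_label = NA_character_,
                                description = "") {
  stopifnot(is.list(sets))
  nm <- names(sets)
  if (length(sets) > 0 && (is.null(nm) || any(nm == "") || anyNA(nm))) {
    stop("every gene set must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate set name: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  category <- rep_len(as.character(category), length(sets))
  bad <- setdiff(unique(category), gene_set_categories())
  if (length(sets) > 0 && length(bad) > 0) {
    stop("unknown gene-set category: ", paste(bad, collapse = ", "))
  }
  tf_label <- rep_len(as.character(tf_label), length(sets))
  description <- rep_len(as.character(description), length(sets))
  sets <- lapply(sets, function(g) {
    g <- unique(toupper(as.character(g)))
    g <- g[!is.na(g) & g != ""]
    if (length(g) == 0) stop("gene sets must be non-empty")
    g
  })
  structure(
    list(
      sets = sets,
      info = data.frame(
        name = nm %||% character(0), category = category, tf_label = tf_label,
        description = description, stringsAsFactors = FALSE
      )
    ),
    class = "gene_set_collection"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname gene_set_collection
#' @export
gene_set_categories <- function() {
  c("TFBS", "GO_BP", "GO_CC", "GO_MF", "KEGG", "OTHER")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x), "sets\n")
  if (length(x) > 0) {
    sz <- set_sizes(x)
    cat("  categories:", paste(sprintf("%s (%d)", names(table(x$info$category)),
                                       table(x$info$category)), collapse = ", "), "\n")
    cat("  set sizes: ", min(sz), "-", max(sz), " genes\n", sep = "")
    cat("  universe:", length(collection_universe(x)), "distinct genes\n")
  }
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$info$name)
  if (anyNA(i)) stop("unknown set name")
  gene_set_collection(x$sets[i],
    category = x$info$category[i],
    tf_label = x$info$tf_label[i],
    description = x$info$description[i]
  )
}

#' Sizes and universe of a collection
#'
#' `set_sizes` returns the number of genes per set; `collection_universe`
#' returns the union of all member genes.
#'
#' @param x A `gene_set_collection`.
#' @return An integer vector (named by set) or a character vector of genes.
#' @export
set_sizes <- function(x) {
  stopifnot(inherits(x, "gene_set_collection"))
  vapply(x$sets, length, integer(1))
}

#' @rdname set_sizes
#' @export
collection_universe <- function(x) {
  stopifnot(inherits(x, "gene_set_collection"))
  unique(unlist(x$sets, use.names = FALSE)) %||% character(0)
}

#' Read gene sets from a GMT file
#'
#' GMT is the tab-separated gene-set format (set name, description, then
#' one field per member gene). Member symbols are upper-cased and
#' duplicates within a line collapsed.
#'
#' @param path Path to a GMT file.
#' @param category Category assigned to every set read (see
#'   [gene_set_collection()]).
#' @param tf_label Optional named character vector mapping set names to TF
#'   labels, or a single value recycled to all sets.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, category = "OTHER", tf_label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(gene_set_collection(stats::setNames(list(), character(0))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed GMT line (fewer than 3 tab-separated fields) at line ",
         which(nf < 3)[1])
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    stop("duplicate set name in GMT file: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), nm)
  tf <- if (!is.null(names(tf_label))) unname(tf_label[nm]) else tf_label
  gene_set_collection(sets, category = category, tf_label = tf, description = desc)
}

#' Write gene sets to a GMT file
#'
#' @param x A `gene_set_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(seq_along(x$sets), function(i) {
    paste(c(x$info$name[i], x$info$description[i], x$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets by size
#'
#' Retains sets whose size falls within `[min_size, max_size]`. When a
#' `universe` is supplied (typically the genes measured in the expression
#' compendium), sizes are measured after intersecting each set with it, so
#' sets with too few measurable genes are dropped; the stored memberships
#' are left untouched.
#'
#' @param x A `gene_set_collection`.
#' @param min_size,max_size Inclusive size bounds (defaults 10 and 500).
#' @param universe Optional character vector of gene symbols against which
#'   sizes are measured.
#' @return A filtered `gene_set_collection`.
#' @export
filter_by_size <- function(x, min_size = 10, max_size = 500, universe = NULL) {
  stopifnot(inherits(x, "gene_set_collection"))
  if (min_size < 1 || max_size < min_size) {
    stop("require min_size >= 1 and max_size >= min_size")
  }
  if (length(x) == 0) return(x)
  sz <- if (is.null(universe)) {
    set_sizes(x)
  } else {
    universe <- toupper(universe)
    vapply(x$sets, function(g) sum(g %in% universe), integer(1))
  }
  keep <- which(sz >= min_size & sz <= max_size)
  x[keep]
}

#' Add per-TF union ("_all") TFBS sets
#'
#' A transcription factor can bind several distinct motifs, each with its
#' own TFBS gene set. For every TF labelled on two or more sets, this
#' appends a set named `<TF>_all` holding the union of that TF's TFBS
#' sets; original sets are retained. Union sets take part in all
#' downstream tests exactly like ordinary TFBS sets.
#'
#' @param x A `gene_set_collection` whose TFBS sets carry `tf_label`.
#' @return The collection with union sets appended.
#' @export
build_tf_union_sets <- function(x) {
  stopifnot(inherits(x, "gene_set_collection"))
  if (length(x) == 0) return(x)
  lab <- x$info$tf_label
  tfs <- names(which(table(lab[!is.na(lab)]) >= 2))
  if (length(tfs) == 0) return(x)
  tfs <- tfs[!paste0(tfs, "_all") %in% x$info$name]
  if (length(tfs) == 0) return(x)
  union_sets <- lapply(tfs, function(tf) {
    unique(unlist(x$sets[which(lab == tf)], use.names = FALSE))
  })
  names(union_sets) <- paste0(tfs, "_all")
  n_member <- vapply(tfs, function(tf) sum(lab == tf, na.rm = TRUE), integer(1))
  unions <- gene_set_collection(
    union_sets, category = "TFBS", tf_label = tfs,
    description = sprintf("union of %d TFBS sets for %s", n_member, tfs)
  )
  gene_set_collection(
    c(x$sets, unions$sets),
    category = c(x$info$category, unions$info$category),
    tf_label = c(x$info$tf_label, unions$info$tf_label),
    description = c(x$info$description, unions$info$description)
  )
}
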