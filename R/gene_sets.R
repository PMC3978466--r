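#' Read a gene-set collection from a GMT file
#'
#' GMT is the standard tab-separated gene-set format: one set per line with
#' the set identifier, a free-text description, then one gene symbol per
#' field. Duplicate member symbols within a line are collapsed and empty
#' member fields are dropped.
#'
#' @param path Path to a GMT file.
#' @return A gene-set collection: a tibble with one row per set and columns
#'   `set_id`, `name`, `source` (database prefix such as `GO`, `NC`, `PF`,
#'   `KE`, `BC`, `RE`, `TF`, `MI`, `GB`, or `user`) and `genes`, a
#'   list-column of unique member symbols.
#' @export
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines("GO_0000001\tdemo\tg1\tg2\tg2", gmt)
#' read_gmt(gmt)
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("GMT file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(set_id = character(), name = character(),
                  source = character(), genes = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(paste0("Malformed GMT line ", bad[1L],
                 ": fewer than 3 tab-separated fields"))
  }
  ids <- map_chr(fields, 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(paste0("Duplicate gene-set id in GMT: ", dup[1L]))
  }
  genes <- map(fields, function(f) {
    g <- f[-(1:2)]
    unique(g[nzchar(g)])
  })
  empty <- which(lengths(genes) == 0L)
  if (length(empty) > 0L) {
    abort(paste0("Gene set ", ids[empty[1L]], " has no members"))
  }
  tibble(
    set_id = ids,
    name = map_chr(fields, 2L),
    source = gs_source(ids),
    genes = genes
  )
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets A gene-set collection tibble (see [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(all(c("set_id", "genes") %in% names(sets)))
  name <- if ("name" %in% names(sets)) sets$name else sets$set_id
  lines <- map_chr(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_id[i], name[i], sets$genes[[i]]), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

gs_source <- function(ids) {
  known <- c("GO", "NC", "PF", "KE", "BC", "RE", "TF", "MI", "GB")
  prefix <- toupper(sub("[_:].*$", "", ids))
  out <- rep("user", length(ids))
  out[prefix %in% known] <- prefix[prefix %in% known]
  out
}

#' Restrict gene sets to detected genes and filter by size
#'
#' Each set's members are first intersected with the universe of detected
#' genes; sets are then retained only if the detected size is strictly
#' greater than `min_excl` and strictly smaller than `max_excl`. Both bounds
#' are exclusive, so with the defaults a set needs at least 11 and at most
#' 999 detected members.
#'
#' @param sets A gene-set collection tibble.
#' @param universe Character vector of detected gene symbols.
#' @param min_excl,max_excl Exclusive size bounds (defaults 10 and 1000).
#' @return The filtered collection, with `genes` replaced by the
#'   intersection with `universe` and a `detected_size` column added.
#' @export
filter_gene_sets <- function(sets, universe, min_excl = 10L, max_excl = 1000L) {
  if (length(universe) == 0L) abort("`universe` must be non-empty")
  universe <- unique(universe)
  out <- sets
  out$genes <- map(out$genes, intersect, y = universe)
  out$detected_size <- lengths(out$genes)
  out[out$detected_size > min_excl & out$detected_size < max_excl, , drop = FALSE]
}
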