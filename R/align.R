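#' Scoring scheme for local protein alignment
#'
#' Defaults follow blastp's protein defaults: BLOSUM62 with gap open 11 and
#' gap extend 1 (a gap of length k costs `gap_open + k * gap_extend`).
#' Rows/columns of the matrix involving `X` are forced to 0 so ambiguity
#' never scores, positively or negatively.
#'
#' @param matrix_name Name of a bundled matrix (`"BLOSUM62"`, `"BLOSUM45"`,
#'   `"BLOSUM80"`, `"PAM250"`) — resolved from Biostrings' data — or ignored
#'   when `matrix` is given.
#' @param gap_open,gap_extend Positive integer penalties,
#'   `gap_open >= gap_extend >= 1`.
#' @param matrix Optional explicit integer substitution matrix with
#'   single-letter dimnames (e.g. from [read_score_matrix()]).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L, matrix = NULL) {
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (!(gap_open >= gap_extend && gap_extend >= 1L))
    abort_fmt("need gap_open >= gap_extend >= 1 (got %d, %d)",
              gap_open, gap_extend)
  if (is.null(matrix)) {
    env <- new.env()
    ok <- tryCatch({
      utils::data(list = matrix_name, package = "Biostrings", envir = env)
      TRUE
    }, warning = function(w) FALSE)
    if (!ok || !exists(matrix_name, envir = env))
      abort_fmt("unknown substitution matrix: %s", matrix_name)
    matrix <- get(matrix_name, envir = env)
  }
  mat <- as.matrix(matrix)
  storage.mode(mat) <- "integer"
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
  }
  structure(list(matrix_name = matrix_name, gap_open = gap_open,
                 gap_extend = gap_extend, matrix = mat),
            class = "scoring_scheme")
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix layout used by NCBI BLAST data
#' files: `#` comment lines, a header row of column letters, then one row
#' per letter.
#'
#' @param path Path to the matrix file.
#' @return Integer matrix with letter dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  rows <- vapply(body, `[`, "", 1)
  vals <- t(vapply(body, function(x) as.integer(x[-1]),
                   integer(length(cols))))
  dimnames(vals) <- list(rows, cols)
  vals
}

encode_seq <- function(s, alphabet) {
  ch <- strsplit(toupper(s), "")[[1]]
  idx <- match(ch, alphabet)
  if (anyNA(idx)) {
    xi <- match("X", alphabet)
    if (is.na(xi))
      abort_fmt("character '%s' not in scoring alphabet", ch[is.na(idx)][1])
    idx[is.na(idx)] <- xi
  }
  idx - 1L
}

#' Optimal affine-gap local alignment of two proteins
#'
#' Smith--Waterman with Gotoh affine gaps; the optimum is found exactly
#' (no heuristic seeding).  Traceback is deterministic: ties prefer the
#' diagonal move, then the vertical (query-consuming), then the horizontal.
#' `overlap` counts only residue-residue columns, matching the
#' overlap-length readout of blastp-style displays; `identity_pct` is
#' `100 * matches / overlap`, with `X` never counted as a match.
#'
#' @param query,target Non-empty amino-acid strings.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `alignment_result` (fields `score`,
#'   `identity_pct`, `overlap`, `matches`, `coverage_query`,
#'   `coverage_target`, and 0-based half-open `query_span`/`target_span`),
#'   or `NULL` when no alignment scores above zero (no hit).
#' @export
local_align <- function(query, target, scheme = scoring_scheme()) {
  if (!nzchar(query) || !nzchar(target))
    abort_fmt("local_align: empty sequence")
  alpha <- rownames(scheme$matrix)
  q <- encode_seq(query, alpha)
  t <- encode_seq(target, alpha)
  xcode <- match("X", alpha, nomatch = 0L) - 1L
  res <- sw_align_cpp(q, t, scheme$matrix, scheme$gap_open,
                      scheme$gap_extend, xcode)
  if (!res$hit) return(NULL)
  structure(list(
    score = res$score,
    identity_pct = 100 * res$matches / res$overlap,
    overlap = res$overlap,
    matches = res$matches,
    coverage_query = res$overlap / nchar(query),
    coverage_target = res$overlap / nchar(target),
    query_span = c(res$query_start - 1L, res$query_end),
    target_span = c(res$target_start - 1L, res$target_end)),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment> score %d, identity %.1f%%, overlap %d, cov %.2f/%.2f\n",
    x$score, x$identity_pct, x$overlap, x$coverage_query,
    x$coverage_target))
  invisible(x)
}

# k-mer sets for the shared-word prefilter
protein_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1), k:n))
}

#' Best alignment hit of a query against a genome
#'
#' Aligns the query against every protein of the target genome and returns
#' the top scorer.  Ties are broken by higher identity, then by
#' lexicographically smallest gene id.  The optional k-mer prefilter skips
#' only targets sharing no length-`k` word with the query (a documented
#' heuristic); `prefilter = FALSE` is the exact reference behaviour.
#'
#' @param query A `gene_record` or a plain protein string.
#' @param target A `genome`.
#' @param scheme A [scoring_scheme()].
#' @param prefilter Use the shared k-mer screen (default TRUE).
#' @param k Word length of the prefilter.
#' @return `list(gene_id =, alignment =)` or `NULL` when nothing aligns.
#' @export
best_hit <- function(query, target, scheme = scoring_scheme(),
                     prefilter = TRUE, k = 4L) {
  qseq <- if (is.character(query)) query else query$protein
  if (!nrow(target$genes)) abort_fmt("best_hit: empty genome")
  ids <- target$genes$gene_id
  seqs <- target$genes$protein
  if (prefilter) {
    qk <- protein_kmers(qseq, k)
    keep <- vapply(seqs, function(s) {
      any(protein_kmers(s, k) %in% qk)
    }, logical(1), USE.NAMES = FALSE)
    ids <- ids[keep]; seqs <- seqs[keep]
    if (!length(ids)) return(NULL)
  }
  best <- NULL
  for (i in seq_along(ids)) {
    al <- local_align(qseq, seqs[i], scheme)
    if (is.null(al)) next
    if (is.null(best) ||
        al$score > best$alignment$score ||
        (al$score == best$alignment$score &&
         (al$identity_pct > best$alignment$identity_pct ||
          (al$identity_pct == best$alignment$identity_pct &&
           ids[i] < best$gene_id)))) {
      best <- list(gene_id = ids[i], alignment = al)
    }
  }
  best
}

#' Write a set of alignment results as TSV
#'
#' @param hits Data frame with columns query, target, and the
#'   `alignment_result` scalar fields.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
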