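# Silicanin sequence architecture, composition and homolog screening.
# Coordinates are 1-based and inclusive throughout.

AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

.as_seq <- function(seq) {
  if (inherits(seq, "AAString") || inherits(seq, "AAStringSet"))
    seq <- as.character(seq)[1L]
  if (!is.character(seq) || length(seq) != 1L)
    stop("sequence must be a single character string")
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, "")[[1L]]), c(AA_STANDARD, "X"))
  if (length(bad))
    stop("sequence contains non-standard residues: ", paste(bad, collapse = ""))
  if (nchar(seq) < 1L) stop("sequence is empty")
  seq
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of uppercase sequences.
#' @export
read_protein <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Annotate silicanin domain architecture
#'
#' Partitions a silicanin precursor into its five canonical segments:
#' signal peptide (SP), the ~30-residue RXL domain ending in an R-x-L
#' tripeptide (canonically RRL, a proteolytic processing mark of diatom
#' biosilica proteins), the long NQ-rich luminal domain, a 20-residue
#' transmembrane helix (TM) and the 20-residue C-terminal cytosolic
#' domain (CYT). TM and CYT are fixed-length C-terminal segments; the SP
#' boundary is either supplied (e.g. from a signal-peptide predictor) or
#' inferred from the RXL rule: the first R-x-L tripeptide ending within
#' residues 20..80 closes a 30-residue RXL domain, which fixes the SP end
#' 30 residues upstream.
#'
#' @param seq Amino-acid sequence (character string or `AAString`).
#' @param sp_end Optional last residue of the signal peptide. If `NULL`,
#'   inferred from the RXL rule.
#' @param id Sequence identifier used in reports.
#' @return An object of class `domain_annotation`: list with `id`,
#'   `length`, `domains` (data frame `label`, `start`, `end`),
#'   `nq_clusters` and `motif_hits` (starts of the GGQKFAL motif).
#' @examples
#' seq <- paste0(strrep("M", 15), strrep("A", 27), "RRL",
#'               strrep("NQ", 170), "C", strrep("I", 20), strrep("K", 20))
#' annotate_architecture(seq)
#' @export
annotate_architecture <- function(seq, sp_end = NULL, id = "query") {
  seq <- .as_seq(seq)
  n <- nchar(seq)
  if (n < 95L)
    stop("sequence too short to host SP/RXL/NQ/TM/CYT architecture (need >= 95 aa)")
  cyt <- c(n - 19L, n)
  tm <- c(n - 39L, n - 20L)
  if (is.null(sp_end)) {
    # first R-x-L tripeptide end in 20..80 that leaves room for a 30-aa RXL
    ends <- integer(0)
    chars <- strsplit(seq, "")[[1L]]
    for (e in 20:min(80L, n)) {
      if (e >= 3L && chars[e - 2L] == "R" && chars[e] == "L" && e - 30L >= 1L) {
        ends <- e
        break
      }
    }
    if (!length(ends))
      stop("no R-x-L tripeptide ending in residues 20..80; supply 'sp_end'")
    sp_end <- ends - 30L
  }
  sp_end <- as.integer(sp_end)
  if (sp_end < 1L || sp_end + 30L + 40L > n)
    stop("'sp_end' leaves no room for RXL + TM + CYT")
  rxl <- c(sp_end + 1L, sp_end + 30L)
  if (rxl[2L] >= tm[1L]) stop("RXL domain would overlap the transmembrane helix")
  trip <- substr(seq, rxl[2L] - 2L, rxl[2L])
  if (trip != "RRL")
    warning(sprintf("RXL domain ends in '%s', not the canonical 'RRL'", trip))
  nq <- c(rxl[2L] + 1L, tm[1L] - 1L)
  domains <- data.frame(
    label = c("SP", "RXL", "NQ", "TM", "CYT"),
    start = c(1L, rxl[1L], nq[1L], tm[1L], cyt[1L]),
    end = c(sp_end, rxl[2L], nq[2L], tm[2L], cyt[2L]),
    stringsAsFactors = FALSE
  )
  # partition sanity: contiguous, non-overlapping, covering 1..n
  stopifnot(domains$start[1L] == 1L, domains$end[5L] == n,
            all(domains$start[-1L] == domains$end[-5L] + 1L))
  structure(
    list(id = id, length = n, domains = domains,
         nq_clusters = nq_clusters(seq),
         motif_hits = find_motif(seq)),
    class = "domain_annotation"
  )
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat(sprintf("Silicanin domain annotation for '%s' (%d aa)\n", x$id, x$length))
  d <- x$domains
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %-4s %4d-%4d  (%d aa)\n",
                d$label[i], d$start[i], d$end[i], d$end[i] - d$start[i] + 1L))
  cat(sprintf("  %d NQ-rich cluster(s); GGQKFAL motif at: %s\n",
              nrow(x$nq_clusters),
              if (length(x$motif_hits)) paste(x$motif_hits, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Find asparagine/glutamine-rich clusters
#'
#' Slides a window over the sequence and merges all windows whose N+Q
#' fraction reaches `min_fraction` into maximal cluster intervals.
#'
#' @param seq Amino-acid sequence.
#' @param window Window length in residues.
#' @param min_fraction Minimum N+Q fraction within a window.
#' @return Data frame with columns `start`, `end` (possibly zero rows).
#' @export
nq_clusters <- function(seq, window = 10L, min_fraction = 0.5) {
  seq <- .as_seq(seq)
  n <- nchar(seq)
  if (window > n) stop("'window' exceeds sequence length")
  is_nq <- strsplit(seq, "")[[1L]] %in% c("N", "Q")
  cs <- c(0L, cumsum(is_nq))
  starts <- seq_len(n - window + 1L)
  frac <- (cs[starts + window] - cs[starts]) / window
  hit <- starts[frac >= min_fraction]
  if (!length(hit)) return(data.frame(start = integer(0), end = integer(0)))
  # union of qualifying windows [i, i+window-1]
  out_start <- integer(0); out_end <- integer(0)
  cur_s <- hit[1L]; cur_e <- hit[1L] + window - 1L
  for (i in hit[-1L]) {
    if (i <= cur_e + 1L) cur_e <- i + window - 1L
    else {
      out_start <- c(out_start, cur_s); out_end <- c(out_end, cur_e)
      cur_s <- i; cur_e <- i + window - 1L
    }
  }
  data.frame(start = c(out_start, cur_s), end = c(out_end, cur_e))
}

#' Find exact motif occurrences
#'
#' Returns all (possibly overlapping) 1-based start positions of an exact
#' motif match. The default motif is the conserved silicanin heptapeptide
#' GGQKFAL.
#'
#' @param seq Amino-acid sequence.
#' @param motif Motif to search for (plain residues, no wildcards).
#' @return Integer vector of start positions (empty if absent).
#' @export
find_motif <- function(seq, motif = "GGQKFAL") {
  seq <- .as_seq(seq)
  if (!nzchar(motif)) stop("'motif' must be non-empty")
  pat <- paste0("(?=", gsub("([][{}()*+?.\\^$|])", "\\\\\\1", motif), ")")
  m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Residue composition statistics
#'
#' Exact residue counts and the acidic (Asp+Glu) fraction of a sequence
#' interval.
#'
#' @param seq Amino-acid sequence.
#' @param interval Optional `c(start, end)` (1-based inclusive); default
#'   whole sequence.
#' @return List with `counts` (named, all 20 residues plus X), `length`,
#'   `acidic_count`, `acidic_fraction` and `acidic_percent`
#'   (= `round(100 * fraction)`).
#' @export
composition_stats <- function(seq, interval = NULL) {
  seq <- .as_seq(seq)
  n <- nchar(seq)
  if (is.null(interval)) interval <- c(1L, n)
  if (length(interval) != 2L || interval[1L] < 1L || interval[2L] > n ||
      interval[1L] > interval[2L])
    stop("invalid interval")
  sub <- substr(seq, interval[1L], interval[2L])
  chars <- strsplit(sub, "")[[1L]]
  counts <- table(factor(chars, levels = c(AA_STANDARD, "X")))
  counts <- stats::setNames(as.integer(counts), names(counts))
  len <- nchar(sub)
  acidic <- counts[["D"]] + counts[["E"]]
  list(counts = counts, length = len, acidic_count = acidic,
       acidic_fraction = acidic / len,
       acidic_percent = round(100 * acidic / len))
}

#' Default side-chain and terminal pKa values
#'
#' The EMBOSS pKa set, recorded verbatim so isoelectric points are
#' reproducible bit-for-bit.
#'
#' @return Named numeric vector (`Nterm`, `Cterm`, `C`, `D`, `E`, `H`,
#'   `K`, `R`, `Y`).
#' @export
pka_table_default <- function() {
  c(Nterm = 8.6, Cterm = 3.6,
    C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
}

#' Net charge of a peptide at a given pH
#'
#' Henderson--Hasselbalch sum over the free termini and ionizable side
#' chains (C, D, E, H, K, R, Y).
#'
#' @param seq Amino-acid sequence.
#' @param pH pH value(s).
#' @param pka Named pKa vector, see [pka_table_default()].
#' @param termini Include the free N/C termini (default `TRUE`).
#' @return Net charge (same length as `pH`).
#' @export
protein_net_charge <- function(seq, pH, pka = pka_table_default(),
                               termini = TRUE) {
  seq <- .as_seq(seq)
  counts <- table(strsplit(seq, "")[[1L]])
  cnt <- function(a) if (a %in% names(counts)) as.numeric(counts[[a]]) else 0
  pos_frac <- function(pk) 1 / (1 + 10^(pH - pk))
  neg_frac <- function(pk) -1 / (1 + 10^(pk - pH))
  ch <- 0
  if (termini) ch <- pos_frac(pka[["Nterm"]]) + neg_frac(pka[["Cterm"]])
  for (a in c("K", "R", "H")) ch <- ch + cnt(a) * pos_frac(pka[[a]])
  for (a in c("D", "E", "C", "Y")) ch <- ch + cnt(a) * neg_frac(pka[[a]])
  ch
}

#' Isoelectric point by bisection
#'
#' The pH at which the net charge of the peptide crosses zero, found by
#' bisection on pH 0..14. The default tolerance (1e-4 pH units) is well
#' inside the 0.01 pH units conventionally reported, so the returned pI is
#' a numerical zero of the net-charge function.
#'
#' @inheritParams protein_net_charge
#' @param interval Optional `c(start, end)` restricting the computation to
#'   a subsequence (termini are then those of the subsequence).
#' @param tol Bisection tolerance in pH units.
#' @return Estimated pI.
#' @export
isoelectric_point <- function(seq, interval = NULL,
                              pka = pka_table_default(), termini = TRUE,
                              tol = 1e-4) {
  seq <- .as_seq(seq)
  if (!is.null(interval)) {
    if (length(interval) != 2L || interval[1L] < 1L ||
        interval[2L] > nchar(seq) || interval[1L] > interval[2L])
      stop("invalid interval")
    seq <- substr(seq, interval[1L], interval[2L])
  }
  lo <- 0; hi <- 14
  f_lo <- protein_net_charge(seq, lo, pka, termini)
  f_hi <- protein_net_charge(seq, hi, pka, termini)
  if (!(f_lo > 0 && f_hi < 0))
    stop("net charge does not cross zero on pH 0..14")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(seq, mid, pka, termini) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Gotoh global alignment with affine gaps and a lexicographic objective:
# maximize (score, #identities, -#columns). The secondary criteria make the
# reported identity canonical among co-optimal alignments (and symmetric in
# the two sequences). Gap of length L costs open + ext * L (BLAST
# "existence/extension" convention).
.gotoh_lex <- function(a, b, submat, open, ext) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  # each state holds score (s), identities (id), columns (cl)
  new_layer <- function() list(
    s = matrix(NEG, n + 1L, m + 1L),
    id = matrix(0L, n + 1L, m + 1L),
    cl = matrix(0L, n + 1L, m + 1L))
  M <- new_layer(); X <- new_layer(); Y <- new_layer()
  M$s[1L, 1L] <- 0
  for (i in seq_len(n)) {  # gaps in b (consume a)
    X$s[i + 1L, 1L] <- -(open + ext * i); X$cl[i + 1L, 1L] <- i
  }
  for (j in seq_len(m)) {
    Y$s[1L, j + 1L] <- -(open + ext * j); Y$cl[1L, j + 1L] <- j
  }
  lex_pick <- function(s, id, cl) {
    best <- 1L
    for (k in seq_along(s)[-1L]) {
      if (s[k] > s[best] ||
          (s[k] == s[best] && (id[k] > id[best] ||
                               (id[k] == id[best] && cl[k] < cl[best]))))
        best <- k
    }
    best
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- submat[av[i], bv[j]]
      idm <- as.integer(av[i] == bv[j])
      # M: aligned pair
      s3 <- c(M$s[i, j], X$s[i, j], Y$s[i, j]) + sc
      i3 <- c(M$id[i, j], X$id[i, j], Y$id[i, j]) + idm
      c3 <- c(M$cl[i, j], X$cl[i, j], Y$cl[i, j]) + 1L
      k <- lex_pick(s3, i3, c3)
      M$s[i + 1L, j + 1L] <- s3[k]; M$id[i + 1L, j + 1L] <- i3[k]
      M$cl[i + 1L, j + 1L] <- c3[k]
      # X: residue of a over a gap
      s3 <- c(M$s[i, j + 1L] - open - ext, X$s[i, j + 1L] - ext,
              Y$s[i, j + 1L] - open - ext)
      i3 <- c(M$id[i, j + 1L], X$id[i, j + 1L], Y$id[i, j + 1L])
      c3 <- c(M$cl[i, j + 1L], X$cl[i, j + 1L], Y$cl[i, j + 1L]) + 1L
      k <- lex_pick(s3, i3, c3)
      X$s[i + 1L, j + 1L] <- s3[k]; X$id[i + 1L, j + 1L] <- i3[k]
      X$cl[i + 1L, j + 1L] <- c3[k]
      # Y: residue of b over a gap
      s3 <- c(M$s[i + 1L, j] - open - ext, X$s[i + 1L, j] - open - ext,
              Y$s[i + 1L, j] - ext)
      i3 <- c(M$id[i + 1L, j], X$id[i + 1L, j], Y$id[i + 1L, j])
      c3 <- c(M$cl[i + 1L, j], X$cl[i + 1L, j], Y$cl[i + 1L, j]) + 1L
      k <- lex_pick(s3, i3, c3)
      Y$s[i + 1L, j + 1L] <- s3[k]; Y$id[i + 1L, j + 1L] <- i3[k]
      Y$cl[i + 1L, j + 1L] <- c3[k]
    }
  }
  s3 <- c(M$s[n + 1L, m + 1L], X$s[n + 1L, m + 1L], Y$s[n + 1L, m + 1L])
  i3 <- c(M$id[n + 1L, m + 1L], X$id[n + 1L, m + 1L], Y$id[n + 1L, m + 1L])
  c3 <- c(M$cl[n + 1L, m + 1L], X$cl[n + 1L, m + 1L], Y$cl[n + 1L, m + 1L])
  k <- lex_pick(s3, i3, c3)
  list(score = s3[k], identities = i3[k], columns = c3[k])
}

.blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

#' Global pairwise sequence identity
#'
#' Needleman--Wunsch/Gotoh global alignment with affine gap penalties and
#' BLOSUM62 scoring (gap existence 11, extension 1, the classic protein
#' BLAST parameterization). Identity is the number of identical aligned
#' pairs divided by the number of alignment columns (gap columns included).
#' Among co-optimal alignments the one with the most identities (then the
#' fewest columns) defines the reported value, which makes the result
#' deterministic and symmetric.
#'
#' @param a,b Amino-acid sequences.
#' @param gap_open Gap existence penalty (positive).
#' @param gap_extend Gap extension penalty per residue (positive).
#' @param submat Substitution matrix (default BLOSUM62 from Biostrings).
#' @return List with `percent_identity`, `identities`, `columns`, `score`.
#' @examples
#' pairwise_identity("ACDE", "ACDF")$percent_identity
#' @export
pairwise_identity <- function(a, b, gap_open = 11, gap_extend = 1,
                              submat = NULL) {
  a <- .as_seq(a); b <- .as_seq(b)
  if (is.null(submat)) submat <- .blosum62()
  res <- .gotoh_lex(a, b, submat, gap_open, gap_extend)
  res$percent_identity <- 100 * res$identities / res$columns
  res[c("percent_identity", "identities", "columns", "score")]
}

#' Screen BLAST tabular hits for homologs
#'
#' Filters 12-column BLAST tabular output (`-outfmt 6`: qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore)
#' at a strict E-value threshold and counts the distinct species among the
#' retained hits. The species tag is derived from the subject identifier
#' (the part before the first `|`), or can be computed by a caller-supplied
#' function.
#'
#' @param hits Path to a BLAST tabular file, or a data frame with at least
#'   `sseqid` and `evalue` columns.
#' @param threshold Keep rows with `evalue` strictly below this value.
#' @param species_fun Function mapping subject ids to species tags.
#' @return List with `hits` (the retained rows, with a `species` column),
#'   `n_hits` and `n_species`.
#' @export
screen_homologs <- function(hits, threshold = 1e-50,
                            species_fun = function(id) sub("\\|.*$", "", id)) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (is.character(hits) && length(hits) == 1L) {
    lines <- readLines(hits)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- vapply(parts, function(p)
      length(p) == 12L && !is.na(suppressWarnings(as.numeric(p[11L]))),
      logical(1L))
    if (any(!ok))
      warning(sum(!ok), " malformed row(s) skipped")
    parts <- parts[ok]
    if (!length(parts)) {
      df <- stats::setNames(
        data.frame(matrix(nrow = 0L, ncol = 12L)), cols)
    } else {
      df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
      names(df) <- cols
      for (nm in cols[-(1:2)]) df[[nm]] <- as.numeric(df[[nm]])
    }
  } else if (is.data.frame(hits)) {
    df <- hits
    if (!all(c("sseqid", "evalue") %in% names(df)))
      stop("data frame input needs 'sseqid' and 'evalue' columns")
  } else stop("'hits' must be a file path or a data frame")
  if (nrow(df) && any(df$evalue < 0, na.rm = TRUE))
    stop("negative E-values in input")
  kept <- df[!is.na(df$evalue) & df$evalue < threshold, , drop = FALSE]
  kept$species <- if (nrow(kept)) species_fun(kept$sseqid) else character(0)
  list(hits = kept, n_hits = nrow(kept),
       n_species = length(unique(kept$species)))
}

#' Write a domain annotation as GFF-like TSV
#'
#' Columns: seqid, source, label, start, end.
#'
#' @param annotation A `domain_annotation`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_domain_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "domain_annotation"))
  d <- annotation$domains
  df <- data.frame(seqid = annotation$id, source = "silitrace",
                   label = d$label, start = d$start, end = d$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
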