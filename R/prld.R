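#' Scan a protein sequence for prion-like domains
#'
#' PLAAC-style two-state hidden Markov model scan: one state emits residues
#' with the composition of experimentally characterised yeast prion
#' domains, the other with human background frequencies. Posterior
#' (forward-backward) decoding gives a per-residue prion-like probability;
#' detected domains are the maximal runs with probability > 0.5, as drawn
#' in composition plots with a 0.5 cut on the y-axis.
#'
#' The core length sets the expected prion-like state dwell (the HMM's
#' self-transition), so shorter cores permit shorter detected domains.
#'
#' @param sequence amino-acid string over the 20-letter alphabet; `X` is
#'   tolerated and scored neutrally. Must be at least `core_length` long.
#' @param core_length expected minimal prion-domain core, residues
#'   (default 30).
#' @param background `"human"` (the only bundled background table).
#' @param bg_expected_length expected background segment length (residues)
#'   setting the background self-transition (default 500).
#' @param id sequence identifier carried into the result.
#' @return object of class `prld_scan`: list with `id`, `track` (data frame
#'   `position, residue, p_prionlike`), `domains` (data frame `start, end,
#'   length, max_prob`, 1-based inclusive coordinates), `longest_domain_aa`,
#'   and `parameters`.
#' @examples
#' seqs <- paste0(strrep("LEKD", 20), strrep("QN", 25), strrep("LEKD", 20))
#' scan <- scan_prld(seqs)
#' scan$longest_domain_aa
#' @export
scan_prld <- function(sequence, core_length = 30L, background = "human",
                      bg_expected_length = 500, id = "seq") {
  stopifnot(is.character(sequence), length(sequence) == 1L, core_length >= 2L)
  res <- strsplit(toupper(sequence), "")[[1L]]
  if (length(res) < core_length)
    stop(sprintf("sequence shorter than core_length (%d < %d)", length(res), core_length))
  comp <- prld_composition(background)
  bad <- which(!(res %in% c(rownames(comp), "X")))
  if (length(bad))
    stop(sprintf("unknown residues at positions: %s", paste(bad, collapse = ", ")))

  # emission probabilities per position, both states; X scored neutrally
  ix <- match(res, rownames(comp))
  e_prd <- ifelse(is.na(ix), 0.05, comp[ifelse(is.na(ix), 1L, ix), "prionlike"])
  e_bg <- ifelse(is.na(ix), 0.05, comp[ifelse(is.na(ix), 1L, ix), "background"])

  p_pb <- 1 / core_length          # prion-like -> background
  p_bp <- 1 / bg_expected_length   # background -> prion-like
  init <- c(prd = p_bp / (p_bp + p_pb), bg = p_pb / (p_bp + p_pb))
  trans <- matrix(c(1 - p_pb, p_pb, p_bp, 1 - p_bp), 2L, 2L, byrow = TRUE,
                  dimnames = list(c("prd", "bg"), c("prd", "bg")))

  n <- length(res)
  # scaled forward-backward
  alpha <- matrix(0, n, 2L)
  scale <- numeric(n)
  a <- init * c(e_prd[1L], e_bg[1L])
  scale[1L] <- sum(a)
  alpha[1L, ] <- a / scale[1L]
  for (t in 2:n) {
    a <- (alpha[t - 1L, ] %*% trans) * c(e_prd[t], e_bg[t])
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta <- matrix(0, n, 2L)
  beta[n, ] <- 1
  for (t in (n - 1L):1L) {
    b <- trans %*% (c(e_prd[t + 1L], e_bg[t + 1L]) * beta[t + 1L, ])
    beta[t, ] <- b / scale[t + 1L]
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  p_prd <- post[, 1L]

  domains <- runs_above(p_prd, 0.5)
  if (nrow(domains)) {
    domains$max_prob <- vapply(seq_len(nrow(domains)), function(i)
      max(p_prd[domains$start[i]:domains$end[i]]), 0)
  } else domains$max_prob <- numeric()
  structure(list(id = id,
                 track = data.frame(position = seq_len(n), residue = res,
                                    p_prionlike = p_prd),
                 domains = domains,
                 longest_domain_aa = if (nrow(domains)) max(domains$length) else 0L,
                 parameters = list(core_length = core_length,
                                   background = background,
                                   bg_expected_length = bg_expected_length)),
            class = "prld_scan")
}

runs_above <- function(p, cut) {
  above <- p > cut
  if (!any(above)) return(data.frame(start = integer(), end = integer(),
                                     length = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = ends[keep] - starts[keep] + 1L)
}

prld_composition <- function(background = "human") {
  if (!identical(background, "human"))
    stop("only the bundled 'human' background is available")
  path <- system.file("extdata", "prld_composition.tsv", package = "puncta")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- cbind(prionlike = tab$prionlike / sum(tab$prionlike),
             background = tab$background_human / sum(tab$background_human))
  rownames(m) <- tab$aa
  m
}

#' @export
print.prld_scan <- function(x, ...) {
  cat(sprintf("<prld_scan> %s: %d residues, %d domain(s), longest %d aa\n",
              x$id, nrow(x$track), nrow(x$domains), x$longest_domain_aa))
  if (nrow(x$domains)) print(x$domains)
  invisible(x)
}

#' Scan every sequence in a FASTA file for prion-like domains
#'
#' @param fasta_path path to an (uncompressed) amino-acid FASTA file.
#' @inheritParams scan_prld
#' @return named list of [scan_prld()] results.
#' @export
scan_prld_fasta <- function(fasta_path, core_length = 30L, background = "human") {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  out <- lapply(seq_along(seqs), function(i)
    scan_prld(as.character(seqs[[i]]), core_length = core_length,
              background = background, id = names(seqs)[i]))
  stats::setNames(out, names(seqs))
}

#' Write PrLD scan outputs as TSV
#'
#' Writes the per-residue probability track and a BED-like domain table
#' (`id, start, end, length, max_prob`, 1-based inclusive coordinates).
#'
#' @param scans list of `prld_scan` objects (or a single one).
#' @param track_path,domains_path output TSV paths.
#' @return invisibly, the domain table.
#' @export
write_prld_results <- function(scans, track_path, domains_path) {
  if (inherits(scans, "prld_scan")) scans <- list(scans)
  tracks <- do.call(rbind, lapply(scans, function(s)
    cbind(id = s$id, s$track)))
  doms <- do.call(rbind, lapply(scans, function(s) {
    if (nrow(s$domains) == 0L) return(NULL)
    cbind(id = s$id, s$domains)
  }))
  if (is.null(doms)) doms <- data.frame(id = character(), start = integer(),
                                        end = integer(), length = integer(),
                                        max_prob = numeric())
  utils::write.table(tracks, track_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(doms, domains_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(doms)
}
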