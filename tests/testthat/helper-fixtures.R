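library(data.table)

# --- tiny hand-built SAM fixtures -----------------------------------------

sam_header <- function(refs = c(chr1 = 100000L, chr2 = 100000L)) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
}

sam_line <- function(qname, cigar, pos, rname = "chr1", flag = 0L,
                     mapq = 50L, tags = c("NH:i:1")) {
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
  paste(c(qname, flag, rname, pos, mapq, cigar, "*", 0, 0,
          strrep("A", qlen), strrep("I", qlen), tags), collapse = "\t")
}

write_sam <- function(lines, refs = c(chr1 = 100000L, chr2 = 100000L)) {
  path <- tempfile(fileext = ".sam")
  writeLines(c(sam_header(refs), lines), path)
  path
}

# --- independent per-base MD/CIGAR walker (oracle) ------------------------
# Expands the CIGAR base by base and walks the MD string character by
# character; returns 0-based read (SEQ) offsets of substitution mismatches.
# Deliberately a different algorithm from the package's tokenised walker.

md_offsets_oracle <- function(cigar, md) {
  ops <- strsplit(gsub("([A-Z=])", "\\1 ", cigar), " ")[[1]]
  read_off <- 0L
  md_read_off <- integer(0)   # read offset of each M base, in MD-walk order
  md_is_del <- logical(0)
  for (tok in ops) {
    n <- as.integer(substr(tok, 1, nchar(tok) - 1L))
    op <- substr(tok, nchar(tok), nchar(tok))
    if (op %in% c("M", "=", "X")) {
      md_read_off <- c(md_read_off, read_off + seq_len(n) - 1L)
      md_is_del <- c(md_is_del, rep(FALSE, n))
      read_off <- read_off + n
    } else if (op == "D") {
      md_read_off <- c(md_read_off, rep(NA_integer_, n))
      md_is_del <- c(md_is_del, rep(TRUE, n))
    } else if (op %in% c("I", "S")) {
      read_off <- read_off + n
    } # N, H, P: neither read nor MD walk
  }
  out <- integer(0); out_walk <- integer(0)
  i <- 1L; walk <- 0L
  chars <- strsplit(md, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (grepl("[0-9]", ch)) {
      num <- ch
      while (i < length(chars) && grepl("[0-9]", chars[i + 1L])) {
        i <- i + 1L; num <- paste0(num, chars[i])
      }
      walk <- walk + as.integer(num)
    } else if (ch == "^") {
      while (i < length(chars) && grepl("[A-Za-z]", chars[i + 1L])) {
        i <- i + 1L; walk <- walk + 1L
      }
    } else {
      walk <- walk + 1L
      stopifnot(!md_is_del[walk])
      out <- c(out, md_read_off[walk])
      out_walk <- c(out_walk, walk)
    }
    i <- i + 1L
  }
  data.frame(read_off = out, mdpos = out_walk)
}

# --- junction evidence built directly in code -----------------------------

make_evidence <- function(raw, mm = replicate(length(raw), integer(0),
                                              simplify = FALSE),
                          max_read_length = 50L) {
  trimmed <- mapply(function(o, p) if (length(p)) min(p) - 1L else o,
                    raw, mm)
  ev <- data.table(reference = "chr1", intron_start = 1000L,
                   intron_end = 1100L, strand = "+",
                   n_unique = length(raw),
                   raw_overhangs = list(as.integer(raw)),
                   trimmed_overhangs = list(as.integer(trimmed)),
                   mismatch_positions = list(sort(as.integer(unlist(mm)))),
                   max_read_length = as.integer(max_read_length),
                   multiread_ids = list(character(0)))
  setattr(ev, "class", c("junction_evidence", class(ev)))
  ev
}

# --- shared end-to-end fixture (computed once per test run) ---------------

.fixture_cache <- new.env(parent = emptyenv())

reference_fixture <- function() {
  if (!exists("ref", envir = .fixture_cache)) {
    cfg <- simulation_config(seed = 1L)  # defaults: 2000 true / 200 artefactual
    sam <- tempfile(fileext = ".sam")
    sim <- simulate_spliced_dataset(cfg, sam)
    res <- filter_junctions(sam, seed = 1L)
    assign("ref", list(sim = sim, res = res), envir = .fixture_cache)
  }
  get("ref", envir = .fixture_cache)
}
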