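#' @title Synthetic senescence sequencing study generator
#' @description Generates a fully synthetic reference (genome, structural-RNA
#'   annotations, transcriptome) plus raw small RNA and PARE read libraries
#'   with the statistical structure the downstream analysis assumes: planted
#'   hairpin small RNA loci with stage-dependent abundance, structural-RNA
#'   contaminant reads, uniform genomic background, adapter-ligated raw
#'   reads, and 20-nt PARE tags concentrated at predicted cleavage sites.
#'   Every planted quantity is recorded in a truth ledger so tests read
#'   expectations from the generator, never from constants.
#' @name synthetic_data
NULL

#' Senescence stages, in developmental order
#' @export
senescence_stages <- function() {
  c("young", "mature", "early_senescence", "late_senescence")
}

#' The five abundant sen-sRNA mature sequences
#'
#' The published senescence-inducible locus produces five abundant small
#' RNAs (21, 21, 21, 24 and 21 nt). Returned in the DNA alphabet with their
#' printed summed abundances (transcripts per ten million, all eight
#' libraries) as the `abundance` attribute; these drive the default
#' per-sequence shares of the planted fixture locus.
#'
#' @return named character vector of 5 mature sequences.
#' @export
sen_srna_sequences <- function() {
  x <- c(
    "sen-sRNA1" = "UUCUUGAACCUUGGAAGAAAA",
    "sen-sRNA2" = "UCUUGAACCUUGGAAGAAAAC",
    "sen-sRNA3" = "UGCAAGGUUCAAGAACGGAUC",
    "sen-sRNA4" = "UCUUGCAAGGUUCAAGAACGGAUC",
    "sen-sRNA5" = "AUUCGACAAAGUGAAGGGUUU")
  out <- rna_to_dna(x)
  attr(out, "abundance") <- c(8361, 5840, 5435, 2347, 2520)
  out
}

#' Describe a planted small RNA locus
#'
#' A locus plants one or more mature sequences in the synthetic genome (via
#' an inverted-repeat precursor when supplied) and emits reads for them at a
#' per-library fraction `base_fraction * stage_multiplier[stage] * share`.
#'
#' @param name locus id.
#' @param matures named character vector of mature sequences (RNA or DNA).
#' @param share relative abundance of each mature within the locus
#'   (normalized internally); default uniform.
#' @param stage_multiplier named multiplier per stage; the senescence ramp.
#' @param base_fraction library fraction contributed by the whole locus at
#'   multiplier 1.
#' @param known logical; if TRUE the matures enter the miRNA catalog.
#' @param precursor optional precursor sequence; every mature must be an
#'   exact substring. Required when the locus has more than one mature.
#' @param targets optional list of target specs from [target_spec()].
#' @return an object of class `planted_locus`.
#' @export
planted_locus <- function(name, matures, share = NULL,
                          stage_multiplier = c(young = 1, mature = 1,
                                               early_senescence = 1,
                                               late_senescence = 1),
                          base_fraction = 0.005, known = FALSE,
                          precursor = NULL, targets = list()) {
  matures <- rna_to_dna(matures)
  stopifnot(length(matures) >= 1, !is.null(names(matures)),
            !anyDuplicated(names(matures)))
  if (is.null(share)) share <- stats::setNames(rep(1, length(matures)), names(matures))
  share <- share / sum(share)
  stopifnot(all(share >= 0),
            setequal(names(stage_multiplier), senescence_stages()))
  if (is.null(precursor)) {
    if (length(matures) > 1)
      stop("multi-mature locus needs an explicit precursor")
    precursor <- matures[[1]]
  } else {
    precursor <- rna_to_dna(precursor)
    ok <- vapply(matures, function(m) grepl(m, precursor, fixed = TRUE), logical(1))
    if (!all(ok))
      stop("matures must be exact substrings of the precursor: ",
           paste(names(matures)[!ok], collapse = ", "))
  }
  structure(list(name = name, matures = matures, share = share,
                 stage_multiplier = stage_multiplier,
                 base_fraction = base_fraction, known = known,
                 precursor = precursor, targets = targets),
            class = "planted_locus")
}

#' Engineer a target site by inverse application of the penalty rules
#'
#' Starts from the perfect reverse complement of the small RNA and applies
#' lesions (G:U wobbles or mismatches at chosen sRNA positions). The
#' expected penalty score is computed directly from the rule weights
#' (mismatch 1, G:U 0.5, doubled at core positions), independently of the
#' alignment DP that later has to recover it. A G:U lesion is only possible
#' where the sRNA base is G or T/U.
#'
#' @param srna small RNA sequence (RNA or DNA).
#' @param lesions data.frame with columns `pos` (position from the sRNA 5'
#'   end) and `type` ("gu" or "mismatch").
#' @param params scoring constants, see [target_score_params()].
#' @return list with `site` (target-sense DNA sequence) and
#'   `expected_score`.
#' @export
make_target_site <- function(srna, lesions = NULL,
                             params = target_score_params()) {
  s <- strsplit(rna_to_dna(srna), "")[[1]]
  m <- length(s)
  site <- rev(chartr("ACGT", "TGCA", s))  # site[k] pairs s[m - k + 1]
  score <- 0
  if (!is.null(lesions) && nrow(lesions)) {
    for (r in seq_len(nrow(lesions))) {
      i <- lesions$pos[r]
      k <- m - i + 1
      w <- if (i >= params$core[1] && i <= params$core[2]) params$core_mult else 1
      if (lesions$type[r] == "gu") {
        if (s[i] == "G") site[k] <- "T"
        else if (s[i] == "T") site[k] <- "G"
        else stop("G:U lesion impossible at sRNA position ", i)
        score <- score + params$gu * w
      } else if (lesions$type[r] == "mismatch") {
        site[k] <- s[i]  # base paired with itself is never WC nor G:U
        score <- score + params$mismatch * w
      } else stop("unknown lesion type")
    }
  }
  list(site = paste(site, collapse = ""), expected_score = score)
}

#' Declare a target transcript for a planted small RNA
#'
#' @param transcript_id synthetic transcript name.
#' @param srna_id which mature of the locus targets it.
#' @param lesions lesion table passed to [make_target_site()]; NULL plants a
#'   perfect-complement (score 0) site.
#' @param pare_fraction named per-stage fraction of PARE reads that are the
#'   exact 20-nt tag starting at the predicted cleavage site.
#' @param length transcript length (nt).
#' @return a list describing the target, consumed by [build_reference()].
#' @export
target_spec <- function(transcript_id, srna_id, lesions = NULL,
                        pare_fraction = c(young = 0.01, mature = 0.02,
                                          early_senescence = 0.06,
                                          late_senescence = 0.1),
                        length = 1200) {
  stopifnot(setequal(names(pare_fraction), senescence_stages()))
  list(transcript_id = transcript_id, srna_id = srna_id, lesions = lesions,
       pare_fraction = pare_fraction, length = length)
}

# Remove exact antisense occurrences of matures from a precursor by point
# substitution (outside the mature regions themselves), so hairpin loci do
# not self-report reads on both strands.
break_antisense_matches <- function(precursor, matures) {
  protected <- rep(FALSE, nchar(precursor))
  for (m in matures) {
    at <- gregexpr(m, precursor, fixed = TRUE)[[1]]
    for (a in at[at > 0]) protected[a:(a + nchar(m) - 1)] <- TRUE
  }
  rot <- c(A = "C", C = "G", G = "A", T = "A")
  for (m in matures) {
    rc <- revcomp(m)
    repeat {
      at <- gregexpr(rc, precursor, fixed = TRUE)[[1]]
      at <- at[at > 0]
      if (!length(at)) break
      pos <- at[1]:(at[1] + nchar(rc) - 1)
      free <- pos[!protected[pos]]
      if (!length(free)) stop("cannot break antisense match without touching a mature")
      p <- free[ceiling(length(free) / 2)]
      b <- substr(precursor, p, p)
      substr(precursor, p, p) <- rot[[b]]
    }
  }
  precursor
}

#' The default sen-sRNA-like fixture locus
#'
#' Builds an inverted-repeat precursor embedding the five published mature
#' sequences: one arm carries sen-sRNA5 and the overlapping
#' sen-sRNA1/sen-sRNA2 region, the other arm is its reverse complement with
#' the segment opposite sen-sRNA1/2 replaced by sen-sRNA4 (which contains
#' sen-sRNA3), reproducing the nearly perfect inverted repeat of the real
#' locus. Exact antisense copies of any mature are broken by point
#' substitutions so simulated reads map to a single strand. Per-sequence
#' shares follow the printed summed abundances; expression ramps to late
#' senescence. Three tubulin-like synthetic target transcripts carry sites
#' engineered to penalty scores 4.0, 3.5 and 4.0 for sen-sRNA3.
#'
#' @param base_fraction locus read fraction at stage multiplier 1.
#' @param stage_multiplier senescence ramp (late/mature defaults to 10).
#' @return a `planted_locus`.
#' @export
sen_srna_locus <- function(base_fraction = 0.02,
                           stage_multiplier = c(young = 0.05, mature = 0.1,
                                                early_senescence = 0.5,
                                                late_senescence = 1)) {
  m <- sen_srna_sequences()
  segA <- "TTCTTGAACCTTGGAAGAAAAC"  # sen-sRNA1 and sen-sRNA2 overlapped
  sp <- with_seed(5L, list(random_dna(14), random_dna(12), random_dna(20)))
  arm5 <- paste0(sp[[1]], m[["sen-sRNA5"]], sp[[2]], segA, sp[[3]])
  arm3 <- revcomp(arm5)
  a0 <- nchar(sp[[1]]) + nchar(m[["sen-sRNA5"]]) + nchar(sp[[2]])  # segA offset
  lo <- nchar(arm5) - (a0 + nchar(segA)) + 1  # 1-based start of segA's slot in arm3
  sr4 <- m[["sen-sRNA4"]]
  arm3 <- paste0(substr(arm3, 1, lo - 3), sr4,
                 substr(arm3, lo + nchar(segA), nchar(arm3)))
  precursor <- paste0(arm5, "GTTTAAAC", arm3)
  precursor <- break_antisense_matches(precursor, m)
  stopifnot(all(vapply(m, function(s) grepl(s, precursor, fixed = TRUE), logical(1))))
  ab <- attr(m, "abundance")
  targets <- list(
    target_spec("TUA2like", "sen-sRNA3",
                lesions = data.frame(pos = c(1, 6, 14, 17, 20),
                                     type = c("mismatch", "gu", "mismatch",
                                              "gu", "gu"))),
    target_spec("TUA4like", "sen-sRNA3",
                lesions = data.frame(pos = c(2, 14, 16, 20),
                                     type = c("gu", "mismatch", "mismatch", "gu"))),
    target_spec("TUA6like", "sen-sRNA3",
                lesions = data.frame(pos = c(8, 12, 17, 20),
                                     type = c("gu", "mismatch", "gu", "gu"))))
  planted_locus("sen-sRNA", m, share = ab,
                stage_multiplier = stage_multiplier,
                base_fraction = base_fraction, known = FALSE,
                precursor = precursor, targets = targets)
}

#' A panel of known miRNA-like loci for screen calibration
#'
#' Plants random 21-nt matures registered in the catalog, split into
#' senescence-induced (`fold`), senescence-repressed (`1/fold`) and flat
#' profiles, at staggered abundances above the screening floor.
#'
#' @param n_up,n_down,n_flat counts per profile class.
#' @param fold induced/repressed stage ratio relative to mature.
#' @param base_fraction per-locus library fraction at multiplier 1.
#' @param seed RNG seed for the mature sequences.
#' @return list of `planted_locus` objects.
#' @export
mirna_panel <- function(n_up = 3, n_down = 3, n_flat = 6, fold = 8,
                        base_fraction = 0.002, seed = 101L) {
  profs <- c(rep("up", n_up), rep("down", n_down), rep("flat", n_flat))
  seqs <- with_seed(seed, vapply(seq_along(profs), function(i) random_dna(21),
                                 character(1)))
  stopifnot(!anyDuplicated(seqs))
  lapply(seq_along(profs), function(i) {
    mult <- switch(profs[i],
      up = c(young = 1, mature = 1, early_senescence = fold,
             late_senescence = fold),
      down = c(young = 1, mature = 1, early_senescence = 1 / fold,
               late_senescence = 1 / fold),
      flat = c(young = 1, mature = 1, early_senescence = 1,
               late_senescence = 1))
    nm <- sprintf("ath-miRsyn%02d-%s", i, profs[i])
    planted_locus(nm, stats::setNames(seqs[i], nm),
                  stage_multiplier = mult,
                  base_fraction = base_fraction * (1 + (i %% 3)),
                  known = TRUE)
  })
}

#' A miR408-like nutrient-responsive locus with PARE-validated targets
#'
#' A known catalog miRNA rising about sevenfold into senescence, with two
#' perfect-complement target transcripts whose cleavage-tag fraction in the
#' PARE libraries ramps with stage, emulating the increase of cleavage
#' products for its validated targets.
#'
#' @param base_fraction locus read fraction at multiplier 1.
#' @return a `planted_locus`.
#' @export
mir408_like_locus <- function(base_fraction = 0.004) {
  seq408 <- with_seed(408L, random_dna(21))
  ramp <- c(young = 0.005, mature = 0.01, early_senescence = 0.05,
            late_senescence = 0.09)
  planted_locus("ath-miR408like", c("ath-miR408like" = seq408),
                stage_multiplier = c(young = 0.8, mature = 1,
                                     early_senescence = 4, late_senescence = 7),
                base_fraction = base_fraction, known = TRUE,
                targets = list(
                  target_spec("PCYlike", "ath-miR408like", pare_fraction = ramp),
                  target_spec("LAC3like", "ath-miR408like",
                              pare_fraction = ramp / 2)))
}

#' Simulation configuration
#'
#' Defines the whole synthetic study: eight small RNA libraries (leaf and
#' silique at young, mature, early and late senescence), six PARE leaf
#' libraries (young, mature, and duplicated early/late senescence with
#' reduced distinct-sequence complexity), the planted loci, contaminant and
#' background fractions, adapter, and the seed that fully determines every
#' output.
#'
#' @param seed integer master seed.
#' @param n_chromosomes,chrom_length genome shape (total 100 kb by default).
#' @param adapter3 3' adapter ligated onto simulated raw sRNA reads.
#' @param raw_read_length raw sequencer read length (insert + adapter,
#'   truncated).
#' @param srna_depth,pare_depth reads per library.
#' @param tissues tissues to simulate (silique can be dropped for speed).
#' @param planted_loci list of [planted_locus()] objects.
#' @param structural_fraction fraction of reads drawn from annotated
#'   structural-RNA intervals.
#' @param background_fraction cap check only: the residual background
#'   fraction (1 - structural - planted signal) must stay at or above this
#'   value in every library, guaranteeing the planted signal never crowds
#'   out the noise floor.
#' @param pare_offtarget_fraction minimum PARE off-target (uniform transcript
#'   position) fraction; the realized value per stage is
#'   1 - sum of planted tag fractions.
#' @param pare_complexity named per-stage fraction of transcript positions
#'   available to off-target PARE reads; senescence stages default to low
#'   values, emulating the reproducible loss of distinct sequences.
#' @param n_structural,n_transcripts counts of structural-RNA intervals and
#'   decoy transcripts.
#' @param size_profile per-tissue insert length distribution of non-planted
#'   reads (21 nt predominating in leaf, 24 nt in silique).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chrom_length = 200000L,
                              adapter3 = "CTGTAGGCACCATCAAT",
                              raw_read_length = 40L,
                              srna_depth = 1e5,
                              pare_depth = 5e4,
                              tissues = c("leaf", "silique"),
                              planted_loci = c(list(sen_srna_locus(),
                                                    mir408_like_locus()),
                                               mirna_panel()),
                              structural_fraction = 0.15,
                              background_fraction = 0.1,
                              pare_offtarget_fraction = 0.5,
                              pare_complexity = c(young = 1, mature = 1,
                                                  early_senescence = 0.12,
                                                  late_senescence = 0.03),
                              n_structural = 20L,
                              n_transcripts = 20L,
                              size_profile = list(
                                leaf = c("20" = 0.1, "21" = 0.4, "22" = 0.1,
                                         "23" = 0.1, "24" = 0.3),
                                silique = c("20" = 0.1, "21" = 0.25, "22" = 0.1,
                                            "23" = 0.1, "24" = 0.45))) {
  stopifnot(length(planted_loci) == 0 ||
              all(vapply(planted_loci, inherits, logical(1), "planted_locus")),
            structural_fraction >= 0, structural_fraction <= 1,
            srna_depth > 0, pare_depth > 0,
            setequal(names(pare_complexity), senescence_stages()))
  names(planted_loci) <- vapply(planted_loci, `[[`, character(1), "name")
  if (anyDuplicated(names(planted_loci))) stop("duplicate locus names")
  stages <- senescence_stages()
  srna_libraries <- expand.grid(stage = stages, tissue = tissues,
                                stringsAsFactors = FALSE)[, 2:1]
  srna_libraries$depth <- srna_depth
  srna_libraries$library_id <- paste0(
    ifelse(srna_libraries$tissue == "leaf", "L", "S"),
    c(young = "Y", mature = "M", early_senescence = "SeE",
      late_senescence = "SeL")[srna_libraries$stage])
  pare_libraries <- data.frame(
    stage = stages[c(1, 2, 3, 4, 3, 4)],
    replicate = c(1L, 1L, 1L, 1L, 2L, 2L), stringsAsFactors = FALSE)
  pare_libraries$depth <- pare_depth
  pare_libraries$library_id <- paste0(
    "P", c(young = "Y", mature = "M", early_senescence = "SeE",
           late_senescence = "SeL")[pare_libraries$stage],
    ifelse(pare_libraries$stage %in% stages[3:4], pare_libraries$replicate, ""))
  cfg <- structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length), adapter3 = rna_to_dna(adapter3),
    raw_read_length = as.integer(raw_read_length),
    srna_libraries = srna_libraries, pare_libraries = pare_libraries,
    planted_loci = planted_loci,
    structural_fraction = structural_fraction,
    background_fraction = background_fraction,
    pare_offtarget_fraction = pare_offtarget_fraction,
    pare_complexity = pare_complexity,
    n_structural = as.integer(n_structural),
    n_transcripts = as.integer(n_transcripts),
    size_profile = size_profile), class = "simulation_config")
  # every library must keep room for the background floor
  for (st in stages) {
    sig <- signal_fractions(cfg, st)
    bg <- 1 - structural_fraction - sum(sig$fraction)
    if (bg < background_fraction)
      stop("planted signal leaves background fraction ", round(bg, 3),
           " < background_fraction at stage ", st)
  }
  cfg
}

# per-(locus, mature) absolute read fractions at one stage
signal_fractions <- function(config, stage) {
  out <- lapply(config$planted_loci, function(loc) {
    data.frame(locus = loc$name, mature_id = names(loc$matures),
               sequence = unname(loc$matures),
               fraction = loc$base_fraction * loc$stage_multiplier[[stage]] *
                 unname(loc$share),
               stringsAsFactors = FALSE)
  })
  out <- out[vapply(out, NROW, integer(1)) > 0]
  if (!length(out))
    return(data.frame(locus = character(), mature_id = character(),
                      sequence = character(), fraction = numeric()))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build the synthetic reference and truth ledger
#'
#' Generates the genome with every planted precursor embedded at a recorded
#' position, structural-RNA intervals (GFF3 types tRNA/rRNA/snoRNA/snRNA)
#' disjoint from planted loci, a transcriptome of decoy transcripts plus
#' engineered target transcripts, and the truth ledger (planted matures
#' with positions and per-library expected abundance; targets with expected
#' penalty score and cleavage site).
#'
#' @param config a [simulation_config()].
#' @return an object of class `sim_reference`: list with `genome` (named
#'   character), `annotations` (GRanges), `transcriptome` (named character),
#'   `ledger` (list of data.frames: `matures`, `expression`, `targets`,
#'   `libraries`) and `config`.
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, 1L), {
    chroms <- stats::setNames(
      vapply(seq_len(config$n_chromosomes), function(i)
        random_dna(config$chrom_length), character(1)),
      paste0("chr", seq_len(config$n_chromosomes)))

    loci <- config$planted_loci
    n_loci <- length(loci)
    occupied <- vector("list", length(chroms))  # IRanges of used intervals
    for (i in seq_along(chroms)) occupied[[i]] <- IRanges::IRanges()
    mat_rows <- list()
    place_rows <- list()
    if (n_loci) {
      chrom_of <- rep(seq_along(chroms), length.out = n_loci)
      for (k in seq_len(n_loci)) {
        loc <- loci[[k]]
        ci <- chrom_of[k]
        slot <- which(chrom_of == ci)
        pos <- floor(config$chrom_length *
                       (match(k, slot)) / (length(slot) + 1)) + 1L
        prec <- loc$precursor
        if (pos + nchar(prec) - 1 > config$chrom_length)
          stop("precursor does not fit on chromosome")
        substr(chroms[[ci]], pos, pos + nchar(prec) - 1L) <- prec
        occupied[[ci]] <- c(occupied[[ci]],
                            IRanges::IRanges(pos, pos + nchar(prec) - 1L))
        place_rows[[k]] <- data.frame(
          locus = loc$name, chrom = names(chroms)[ci], start = pos,
          end = pos + nchar(prec) - 1L, stringsAsFactors = FALSE)
        for (mi in seq_along(loc$matures)) {
          off <- regexpr(loc$matures[[mi]], prec, fixed = TRUE)
          mat_rows[[length(mat_rows) + 1L]] <- data.frame(
            locus = loc$name, mature_id = names(loc$matures)[mi],
            sequence = unname(loc$matures[[mi]]),
            size = nchar(loc$matures[[mi]]),
            chrom = names(chroms)[ci],
            start = pos + as.integer(off) - 2L,  # 0-based
            strand = "+", known = loc$known, stringsAsFactors = FALSE)
        }
      }
    }
    matures <- if (length(mat_rows)) do.call(rbind, mat_rows) else
      data.frame(locus = character(), mature_id = character(),
                 sequence = character(), size = integer(), chrom = character(),
                 start = integer(), strand = character(), known = logical())

    # structural intervals, disjoint from planted loci
    struct_types <- rep(c("rRNA", "tRNA", "snoRNA", "snRNA"),
                        length.out = config$n_structural)
    srow <- list()
    for (k in seq_len(config$n_structural)) {
      len <- sample(80:160, 1)
      for (try in 1:200) {
        ci <- sample(seq_along(chroms), 1)
        st <- sample(config$chrom_length - len, 1)
        cand <- IRanges::IRanges(st, st + len - 1L)
        if (!length(IRanges::findOverlaps(cand, occupied[[ci]]))) {
          occupied[[ci]] <- c(occupied[[ci]], cand)
          srow[[k]] <- data.frame(chrom = names(chroms)[ci], start = st,
                                  end = st + len - 1L, type = struct_types[k],
                                  stringsAsFactors = FALSE)
          break
        }
        if (try == 200) stop("could not place structural interval")
      }
    }
    sdf <- do.call(rbind, srow)
    ann <- GenomicRanges::GRanges(
      sdf$chrom, IRanges::IRanges(sdf$start, sdf$end), strand = "+",
      type = sdf$type, ID = sprintf("struct%02d", seq_len(nrow(sdf))))
    if (length(place_rows)) {
      pdf <- do.call(rbind, place_rows)
      loci_gr <- GenomicRanges::GRanges(
        pdf$chrom, IRanges::IRanges(pdf$start, pdf$end), strand = "+",
        type = "gene", ID = pdf$locus)
      ann <- c(ann, loci_gr)
    }

    # transcriptome: decoys + engineered targets
    tx <- stats::setNames(
      vapply(seq_len(config$n_transcripts), function(i)
        random_dna(sample(800:1500, 1)), character(1)),
      sprintf("TXDECOY%02d", seq_len(config$n_transcripts)))
    trow <- list()
    for (loc in loci) {
      for (tg in loc$targets) {
        srna <- loc$matures[[tg$srna_id]]
        if (is.null(srna)) stop("target srna_id not among matures: ", tg$srna_id)
        made <- make_target_site(srna, tg$lesions)
        body <- random_dna(tg$length)
        site_start <- as.integer(tg$length %/% 2)
        site_end <- site_start + nchar(made$site) - 1L
        substr(body, site_start, site_end) <- made$site
        tx[[tg$transcript_id]] <- body
        cleave <- site_end - 9L  # paired to sRNA position 10
        trow[[length(trow) + 1L]] <- data.frame(
          locus = loc$name, srna_id = tg$srna_id, srna = unname(srna),
          transcript_id = tg$transcript_id,
          site_start = site_start, site_end = site_end,
          expected_score = made$expected_score, cleavage_pos = cleave,
          stringsAsFactors = FALSE)
      }
    }
    targets <- if (length(trow)) do.call(rbind, trow) else
      data.frame(locus = character(), srna_id = character(), srna = character(),
                 transcript_id = character(), site_start = integer(),
                 site_end = integer(), expected_score = numeric(),
                 cleavage_pos = integer())
    pare_frac <- do.call(rbind, lapply(loci, function(loc) {
      if (!length(loc$targets)) return(NULL)
      do.call(rbind, lapply(loc$targets, function(tg) {
        data.frame(transcript_id = tg$transcript_id, srna_id = tg$srna_id,
                   stage = senescence_stages(),
                   fraction = unname(tg$pare_fraction[senescence_stages()]),
                   stringsAsFactors = FALSE)
      }))
    }))
    if (is.null(pare_frac))
      pare_frac <- data.frame(transcript_id = character(), srna_id = character(),
                              stage = character(), fraction = numeric())

    # expected abundance per (mature, library)
    libs <- config$srna_libraries
    expr <- do.call(rbind, lapply(seq_len(nrow(libs)), function(i) {
      sf <- signal_fractions(config, libs$stage[i])
      if (!nrow(sf)) return(NULL)
      sf$library_id <- libs$library_id[i]
      sf$tissue <- libs$tissue[i]
      sf$stage <- libs$stage[i]
      sf$expected_tp2m <- sf$fraction / (1 - config$structural_fraction) * 2e6
      sf
    }))
    if (is.null(expr))
      expr <- data.frame(locus = character(), mature_id = character(),
                         sequence = character(), fraction = numeric(),
                         library_id = character(), tissue = character(),
                         stage = character(), expected_tp2m = numeric())
    lib_ledger <- libs
    lib_ledger$structural_fraction <- config$structural_fraction
    lib_ledger$signal_fraction <- vapply(
      libs$stage, function(st) sum(signal_fractions(config, st)$fraction),
      numeric(1))
    lib_ledger$background_fraction <-
      1 - lib_ledger$structural_fraction - lib_ledger$signal_fraction

    structure(list(genome = chroms, annotations = ann, transcriptome = tx,
                   ledger = list(matures = matures, expression = expr,
                                 targets = targets, pare = pare_frac,
                                 libraries = lib_ledger),
                   config = config),
              class = "sim_reference")
  })
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("sim_reference:", length(x$genome), "chromosomes (",
      sum(nchar(x$genome)), "nt ),", length(x$annotations), "annotations,",
      length(x$transcriptome), "transcripts,",
      nrow(x$ledger$matures), "planted matures\n")
  invisible(x)
}

sample_sized_inserts <- function(n, profile) {
  lens <- as.integer(names(profile))
  sample(lens, n, replace = TRUE, prob = profile)
}

#' Simulate one raw small RNA library
#'
#' Draws `depth` reads as a multinomial over planted matures (at their
#' stage-specific fractions), structural-RNA intervals and uniform genomic
#' background, ligates the 3' adapter and truncates to the raw read length.
#'
#' @param ref a [build_reference()] result.
#' @param tissue,stage library identity (must exist in the design).
#' @return list with `reads` (named character vector), `library_id`,
#'   `tissue`, `stage` and a `component_counts` attribute on `reads`.
#' @export
simulate_srna_library <- function(ref, tissue, stage) {
  config <- ref$config
  libs <- config$srna_libraries
  i <- which(libs$tissue == tissue & libs$stage == stage)
  if (length(i) != 1) stop("unknown tissue/stage: ", tissue, "/", stage)
  depth <- libs$depth[i]
  profile <- config$size_profile[[tissue]]
  sf <- signal_fractions(config, stage)
  p <- c(sf$fraction, structural = config$structural_fraction)
  p <- c(p, background = 1 - sum(p))
  stopifnot(p[["background"]] >= 0)
  sdf <- as.data.frame(ref$annotations[ref$annotations$type %in%
                                         c("tRNA", "rRNA", "snoRNA", "snRNA")])
  sdf$seqnames <- as.character(sdf$seqnames)
  with_seed(derive_seed(config$seed, 10L + i), {
    counts <- as.vector(rmultinom(1, depth, p))
    inserts <- character(0)
    if (nrow(sf)) inserts <- rep(sf$sequence, counts[seq_len(nrow(sf))])
    n_struct <- counts[length(counts) - 1L]
    if (n_struct > 0) {
      iv <- sample(nrow(sdf), n_struct, replace = TRUE)
      len <- pmin(sample_sized_inserts(n_struct, profile), sdf$width[iv])
      off <- floor(stats::runif(n_struct) * (sdf$width[iv] - len + 1))
      s <- substring(ref$genome[sdf$seqnames[iv]],
                     sdf$start[iv] + off, sdf$start[iv] + off + len - 1)
      neg <- stats::runif(n_struct) < 0.5
      s[neg] <- revcomp(s[neg])
      inserts <- c(inserts, s)
    }
    n_bg <- counts[length(counts)]
    if (n_bg > 0) {
      ci <- sample(length(ref$genome), n_bg, replace = TRUE,
                   prob = nchar(ref$genome))
      len <- sample_sized_inserts(n_bg, profile)
      st <- floor(stats::runif(n_bg) * (nchar(ref$genome)[ci] - len + 1)) + 1L
      s <- substring(ref$genome[ci], st, st + len - 1)
      neg <- stats::runif(n_bg) < 0.5
      s[neg] <- revcomp(s[neg])
      inserts <- c(inserts, s)
    }
    raw <- substr(paste0(inserts, config$adapter3,
                         strrep("A", config$raw_read_length)),
                  1L, config$raw_read_length)
    names(raw) <- sprintf("%s_read%06d", libs$library_id[i], seq_along(raw))
    attr(raw, "component_counts") <- c(
      signal = if (nrow(sf)) sum(counts[seq_len(nrow(sf))]) else 0L,
      structural = n_struct, background = n_bg)
    list(reads = raw, library_id = libs$library_id[i], tissue = tissue,
         stage = stage, depth = depth)
  })
}

#' Simulate one 20-nt PARE library
#'
#' Signal reads are the exact 20-nt transcript substring whose 5' end is the
#' predicted cleavage site (target base paired to sRNA position 10) of each
#' planted target, at that target's per-stage tag fraction. Off-target reads
#' start uniformly on transcript positions drawn from a per-stage restricted
#' position pool (`pare_complexity`), emulating the loss of
#' distinct-sequence complexity in senescing libraries; the pool is shared
#' between replicates of a stage.
#'
#' @param ref a [build_reference()] result.
#' @param stage senescence stage.
#' @param replicate replicate number within the stage design.
#' @return list with `reads`, `library_id`, `stage`, `replicate`.
#' @export
simulate_pare_library <- function(ref, stage, replicate = 1L) {
  config <- ref$config
  libs <- config$pare_libraries
  i <- which(libs$stage == stage & libs$replicate == replicate)
  if (length(i) != 1) stop("unknown PARE stage/replicate")
  depth <- libs$depth[i]
  pare <- ref$ledger$pare
  sig <- pare[pare$stage == stage & pare$fraction > 0, , drop = FALSE]
  if (nrow(sig) &&
      !all(sig$transcript_id %in% names(ref$transcriptome)))
    stop("declared target transcript absent from transcriptome")
  off_frac <- 1 - sum(sig$fraction)
  stopifnot(off_frac >= 0)
  # off-target position pool, shared across replicates of the stage
  txlen <- nchar(ref$transcriptome)
  npos <- pmax(txlen - 19L, 0L)
  pool_tx <- rep(seq_along(txlen), npos)
  pool_pos <- unlist(lapply(npos, seq_len), use.names = FALSE)
  keep_n <- max(1L, ceiling(config$pare_complexity[[stage]] * length(pool_tx)))
  st_idx <- match(stage, senescence_stages())
  keep <- with_seed(derive_seed(config$seed, 500L + st_idx),
                    sample(length(pool_tx), keep_n))
  with_seed(derive_seed(config$seed, 600L + i), {
    p <- c(sig$fraction, offtarget = off_frac)
    counts <- as.vector(rmultinom(1, depth, p))
    reads <- character(0)
    if (nrow(sig)) {
      cl <- ref$ledger$targets$cleavage_pos[
        match(sig$transcript_id, ref$ledger$targets$transcript_id)]
      tags <- substr(ref$transcriptome[sig$transcript_id], cl, cl + 19L)
      reads <- rep(unname(tags), counts[seq_len(nrow(sig))])
    }
    n_off <- counts[length(counts)]
    if (n_off > 0) {
      pick <- keep[sample(length(keep), n_off, replace = TRUE)]
      reads <- c(reads,
                 unname(substring(ref$transcriptome[pool_tx[pick]],
                                  pool_pos[pick], pool_pos[pick] + 19L)))
    }
    names(reads) <- sprintf("%s_tag%06d", libs$library_id[i], seq_along(reads))
    attr(reads, "component_counts") <- c(
      signal = if (nrow(sig)) sum(counts[seq_len(nrow(sig))]) else 0L,
      offtarget = n_off)
    list(reads = reads, library_id = libs$library_id[i], stage = stage,
         replicate = replicate, depth = depth)
  })
}

#' Write a synthetic reference and its libraries to disk
#'
#' Emits genome FASTA, annotation GFF3 (1-based inclusive), transcriptome
#' FASTA, truth-ledger TSVs, a miRNA catalog FASTA (known planted matures)
#' and raw FASTQ per library.
#'
#' @param ref a [build_reference()] result.
#' @param outdir output directory (created if needed).
#' @param libraries logical; also simulate and write all FASTQ libraries.
#' @return invisibly, the output directory.
#' @export
write_reference <- function(ref, outdir, libraries = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ref$genome, file.path(outdir, "genome.fa"))
  write_gff3(ref$annotations, file.path(outdir, "annotations.gff3"))
  write_fasta(ref$transcriptome, file.path(outdir, "transcriptome.fa"))
  cat_df <- ref$ledger$matures[ref$ledger$matures$known, ]
  if (nrow(cat_df))
    write_fasta(stats::setNames(cat_df$sequence, cat_df$mature_id),
                file.path(outdir, "catalog.fa"))
  for (nm in names(ref$ledger))
    write_tsv(ref$ledger[[nm]], file.path(outdir, paste0("ledger_", nm, ".tsv")))
  if (libraries) {
    for (i in seq_len(nrow(ref$config$srna_libraries))) {
      li <- ref$config$srna_libraries[i, ]
      sim <- simulate_srna_library(ref, li$tissue, li$stage)
      write_fastq(sim$reads, file.path(outdir, paste0(li$library_id, ".fastq")))
    }
    for (i in seq_len(nrow(ref$config$pare_libraries))) {
      li <- ref$config$pare_libraries[i, ]
      sim <- simulate_pare_library(ref, li$stage, li$replicate)
      write_fastq(sim$reads, file.path(outdir, paste0(li$library_id, ".fastq")))
    }
  }
  invisible(outdir)
}
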