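fixture <- function(name) {
  p <- system.file("extdata", name, package = "mitorder")
  if (!nzchar(p)) stop("fixture not installed: ", name)
  p
}

chishuiense <- function() {
  read_annotation_table(fixture("sinopotamon_chishuiense_table.tsv"))
}

wushanense <- function() {
  read_annotation_table(fixture("sinopotamon_wushanense_table.tsv"))
}

# all permutations of 1..l (recursive; used by the TDRL oracle tests)
perms_of <- function(l) {
  if (l == 1L) return(list(1L))
  do.call(c, lapply(seq_len(l), function(i)
    lapply(perms_of(l - 1L), function(p) c(i, ifelse(p >= i, p + 1L, p)))))
}

# a small annotated genome with sequence, built by hand:
# two PCGs (one minus-strand), a tRNA, and a CR, on a 120 bp circle
tiny_genome <- function() {
  # plus-strand PCG, 1..30: ATG + 8 codons + TAA
  cds1 <- paste0("ATG", "TTTGGAATTCCCAAAGGGTTTACA", "TAA")
  stopifnot(nchar(cds1) == 30L)
  # minus-strand PCG occupies 41..70; coding sequence read off the minus
  # strand is cds2, so the genome strand holds its reverse complement
  cds2 <- paste0("ATT", "AAATTTGGGCCCACAATTCCCAAA", "TAG")
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  seq <- paste0(cds1,                      #   1..30  cox1 (+)
                strrep("A", 10),           #  31..40  spacer
                rc(cds2),                  #  41..70  nad2 (-)
                "GGGGCCCCAATTAATT",        #  71..86  trnK (+), 16 bp
                strrep("T", 34))           #  87..120 CR
  rec <- data.frame(gene = c("cox1", "nad2", "trnK", "CR"),
                    start = c(1L, 41L, 71L, 87L),
                    end = c(30L, 70L, 86L, 120L),
                    strand = c("+", "-", "+", NA))
  mito_annotation(rec, genome_length = 120L, taxon = "tiny", circular = TRUE,
                  sequence = seq)
}
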