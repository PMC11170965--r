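---
title: "How the codec works: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How the codec works: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligocodec)
```

## The storage model

DNA data storage writes a byte stream into a pool of short synthetic DNA
strings ("oligos"), each independently synthesizable, amplifiable and
sequenceable. Because synthesis and sequencing chemistry degrade on
extreme GC content and on homopolymer runs, and because individual strings
are lost or corrupted along the way, a practical codec has four jobs:

1. **transcoding** bits to nucleotides at a rate close to the 2 bits/nt
   Shannon limit of a 4-letter alphabet;
2. **constraint satisfaction** - every emitted string must keep its GC
   fraction inside a window-wise band and its homopolymer runs below a
   cap;
3. **robustness** - per-string error correction plus cross-string erasure
   redundancy, so the file survives substitutions and whole-string
   dropout;
4. **addressability** - PCR primer sites ("flanks") for random access to
   one file inside a mixed pool, and per-fragment indices for reassembly.

`oligocodec` implements this pipeline end to end, together with a seeded
read simulator and windowed sequence statistics, so that every claim about
the codec can be tested from a clean R session without external data.

## Codec rules and pins

The atomic mapping is a **codec rule**: a bijection between the sixteen
4-bit values (nibbles, the coding units) and the sixteen dinucleotides.
There are \(16! = 20{,}922{,}789{,}888{,}000\) such bijections. A rule is
addressed by its Lehmer-code rank over the canonical orders - nibbles
ascending `0000..1111`, dinucleotides lexicographic with `A<C<G<T` - and
is materialized lazily from that index; the pool is never enumerated.

A **codec pin** is an ordered pair of distinct rules and is the user-held
key: the first rule transcodes odd-numbered coding units, the second the
even-numbered ones. Decoding with the wrong pin yields wrong nibbles
nearly everywhere, which the per-fragment Reed-Solomon syndromes, the
index-range validation and finally the manifest CRC-32 all reject. Pins
are obscurity keys, not cryptography: the codec makes no hardness claims.

The shipped library holds 30,000 pins sampled uniformly from the rule-pair
space under a mutual-distance screen (Hamming distance over the two
concatenated 16-entry mapping tables, threshold 8 of 32 positions; seed
1729). The screen is exact but O(n) rather than O(n^2): a pair closer than
8 must agree on at least 25 of 32 table positions, hence - pigeonhole - on
at least one of eight disjoint 4-position blocks, so hashing the blocks
finds every candidate conflict.

```{r pins}
lib <- generate_pin_library(n_pins = 100, seed = 1729)
pin <- pin_from_library(lib, 42)
pin
```

## Fragment geometry

A string of length \(L\) (default 200 nt) carries two flanks of \(F\) nt
(default 20) and a payload region of \(L - 2F\) nt holding \(2(L-2F)\)
bits, divided equally among \(k\) fragments (default \(k = 2\); 3 and 4
are supported). Each fragment is serialized as

\[ \text{index} \,\|\, \text{payload} \,\|\, \text{RS parity} \]

with all three fields nibble-aligned so coding units never straddle
fields. The index width is the smallest multiple of 4 bits that addresses
all data, pad and parity fragments with headroom (5% plus 8 slots) for
virtual fragments; the RS field holds \(8n\) bits for \(n\) parity bytes
per block (messages longer than one 255-byte RS block are chunked). At
the defaults each fragment owns 160 bits: a 20-bit index for megabyte-
scale jobs, 16 bits of RS parity, and 124 payload bits.

```{r budget}
cfg <- encode_config(pin, seed = 1)
length_budget(cfg, data_bytes = 2^20)[c("per_fragment_bits", "index_bits",
                                        "payload_bits", "rs_bits")]
```

## Merging by coding-unit interleaving

The \(k\) serialized fragments of one string are merged by round-robin
interleaving of their nibble streams: merged unit \(j\) comes from
fragment \(((j-1) \bmod k)+1\). This choice is load-bearing. Under plain
concatenation each fragment would own a contiguous stretch of the emitted
sequence whose bases are a fixed function of its content; for random data
roughly one fragment in five contains a homopolymer run over the cap
somewhere in its own image, and no choice of partner, retry or virtual
fragment could ever fix it - the encoding loop would simply never
terminate. With interleaving, every homopolymer run of 3 nt or more and
every GC window spans units from all \(k\) members, so the screen outcome
depends jointly on the drawn tuple and a failed draw is genuinely worth
redrawing.

Slot order on the wire is the random draw order. The decoder de-interleaves
the \(k\) streams and reads each stream's own index field, so no canonical
order is needed - and fixing one would trap fragments whose leading index
nibbles happen to transcode into a run-extending prefix in a particular
slot (under near-identity rule pairs, every fragment of a small job shares
the same first payload bases for exactly this reason). The exported
`merge_fragments()` still sorts ascending by index when asked, as the
canonical documented form.

## The draw/screen/redraw loop and virtual fragments

Encoding maintains a pool of fragments. Each round draws a random
pairing of the whole pool into \(k\)-tuples, merges, transcodes and
screens them in one vectorized pass; passing tuples are emitted, failing
tuples return to the pool. A fragment that fails `retry_limit` (default
30) consecutive screens, and any leftover when the pool size drops below
\(k\), is paired with freshly generated **virtual fragments**: filler
fragments with random payloads and indices from the reserved range above
the real fragments, which the decoder discards wholesale.

Two refinements keep this loop total:

* **Virtual payload bias.** A low-entropy fragment - a run of zero bytes,
  or the all-zero pad fragment that completes an odd count before XOR
  expansion - transcodes to a GC-extreme half of the sequence. Uniform
  virtual payloads would essentially never pull a 150-nt window back into
  the 40-60% band, so the sampler escalates from uniform toward the GC
  complement of the stuck fragment, weighting each nibble by the GC
  content of its dinucleotide image under the rule at its positions.
* **Virtual index advance.** The virtual's index nibbles sit in the
  emitted sequence; a violation overlapping them cannot be cleared by
  payload redraws, so the index is advanced every few failed attempts
  (skipped indices are discarded at decode like any reserved index).

The screening itself slides the GC window at step 1 - the bounds hold for
*every* window, not just the analysis tiling - and checks homopolymer runs
over the whole payload plus up to `max_homopolymer` bases of flank context
at each junction.

## Robustness layers

The order of protection is: index assignment, then XOR expansion, then
RS parity per fragment (data, pad and parity fragments alike).

**Reed-Solomon.** Byte-symbol RS over GF(256) (primitive polynomial
0x11d, generator roots \(\alpha^0..\alpha^{n-1}\)); \(n\) parity bytes
detect \(n\) byte errors and correct \(\lfloor n/2 \rfloor\). One byte
spans two coding units = 4 nucleotides, so an \(n\)-byte code absorbs up
to \(4n\) substituted bases when the damage is confined to whole symbols;
with interleaving, a 4-nt burst aligned to the unit grid touches at most
one byte in each of the two member fragments, which the default 2-byte
code corrects. Encoding and syndrome checks are vectorized across all
fragments; the Berlekamp-Massey / Chien / Forney machinery runs only on
the (few) fragments with non-zero syndromes. An uncorrectable fragment is
not an error: it becomes an erasure for the XOR layer.

**XOR redundancy.** Consecutive fragment pairs \((f_{2i}, f_{2i+1})\)
emit a parity fragment with the XOR of their payloads, adding one-third
redundancy; parity fragments are peers (own index, own RS parity). Any
triple with exactly one missing member is reconstructed; the decoder
knows the pad fragment's payload is zero, so the pad never consumes
redundancy. When several received fragments claim the same index, the one
that needed the fewest RS corrections wins - a miscorrected fragment
(possible once errors exceed the RS radius) can land on a foreign index,
but the clean copy always reports zero corrections.

## Flanking sequences (random access)

Flank candidates are windows of random templates kept when they satisfy
the primer acceptance ranges: length 20-25 nt, GC 40-60%, melting
temperature 58-70 degrees C, homopolymer runs at most 4. Tm is the
two-state nearest-neighbor model with the unified duplex parameters,
entropic salt correction \(0.368\,(N{-}1)\ln[\mathrm{Na}^+]\), 50 mM
monovalent salt and 0.25 uM total oligo (CT/4 for non-self-complementary
annealing); the routine agrees with an independent implementation of the
same model to well under 0.1 degrees.

Against a concrete encoded pool, candidates whose 3'-terminal hexamer
matches any payload's 5' end (either strand) are removed - on pools large
enough that all 4096 hexamers occur, this screen is uninformative and the
automatic design falls back to the homology ranking alone. Remaining
candidates are ranked by their maximum local-alignment score against the
pool (match +1, mismatch -1, gap -2, both strands; large pools are
subsampled deterministically), and pairs are chosen greedily from the
lowest scores subject to a mutual primer-dimer bound (local score <= 8)
and distinct 3' hexamers. Because every payload of a job begins with the
same few bases (the shared index prefix), the automatic design evaluates
several score-ranked pairs and keeps the one with the fewest flank/payload
junction violations; the handful of strings that still violate are
re-encoded with the junction context in their screen, so flank attachment
never creates a homopolymer violation.

A prebuilt pool of 20,000 cross-checked candidates (mutual Hamming
distance >= 3 among equal-length members) is regenerated deterministically
from seed 97301 on first use and cached; it is not shipped as a file.

## The read pipeline

Decoding from sequencing reads runs filter, rank, cluster, select:

1. `filter_by_flank()` assigns each read to a file by its flanks (at most
   2 mismatches per flank, either orientation) and reverse-complements
   reverse-strand reads.
2. `quality_filter()` removes reads with *more than* 80% of bases below
   Q30 - the rule applied literally; a read at exactly 80% is kept, and a
   stricter threshold is one argument away.
3. `length_mode_filter()` keeps the modal read length (ties resolve
   toward the manifest's string length); indel-bearing reads fall out
   here.
4. `rank_reads()` deduplicates to unique sequences sorted by quality and
   then by quantity in the multi-pass stable-sort sense: copy number is
   the dominant key, mean Phred quality the tiebreak. The order matters:
   per-read mean quality fluctuates by more (sampling noise across ~200
   bases) than a single erroneous base depresses it, so a quality-first
   sort would shuffle error-free reads at random, while copy number
   separates true strings from their error variants sharply.
5. `cluster_and_select()` clusters greedily in rank order with radius 10%
   of the string length and keeps each cluster's best-ranked member. For
   the equal-length input the pipeline produces, the radius check uses
   Hamming distance and the neighbor search is accelerated exactly by an
   8-block substring index (a sequence within 7 mismatches of an earlier
   one shares at least one block; block mates are accepted as candidate
   parents only if the whole sequences are within the radius, since fixed
   flanks would otherwise link unrelated strings).

The representatives then flow into `decode_file()` as if they were a
clean FASTA.

## What the simulator does and does not emulate

`simulate_reads()` draws a Poisson read count per string at the requested
mean depth (the standard null for shotgun-style sampling), applies
uniform per-base substitutions (default 0.5%, the regime of
chip-synthesized pools read after paired-end merging), optional indels
(default 0), random strand orientation, and Phred profiles in which
erroneous bases score lower (mean Q20 vs Q36). Whole-string dropout is
explicit (`dropout_strings`). It does not model platform-specific error
motifs, position-dependent quality decay, chimeras or coverage bias.
Passing the pipeline on simulated reads therefore demonstrates the
codec's arithmetic - erasure bounds, RS radii, clustering behavior -
under controlled noise, not performance on any particular instrument.

## Problem sizes used by the tests and the acceptance script

The shipped experiments are sized for a single CPU: the coding-potential
measurement encodes 1 MB of seeded pseudorandom bytes (~34,000 strings);
the recovery experiments encode 50 KB (~2,400 strings) and simulate
reads at mean depths 30 and 10 over five seeds; the long-string
constraint experiment encodes an 86,869-byte input into 1000-nt strings;
the pin-library run generates the full 30,000 pins. Module tests use
kilobyte-scale inputs throughout.

## Numerical and policy choices

* **Padding and truth.** The final fragment is zero-padded; the manifest
  records the true byte length and a CRC-32 of the payload, which
  arbitrates wrong-pin detection even with RS disabled.
* **Manifest.** Everything needed to decode except the pin travels on
  the FASTA's first line as `key=value;...`; unknown keys are ignored
  with a warning. The pin never appears in any output artifact.
* **Determinism.** Every random draw - fragment pairing, virtual
  payloads, flank templates, simulated reads - flows from a single
  user-visible seed; identical configuration gives bit-identical output.
* **Retry semantics.** `retry_limit` counts consecutive failed screens
  per fragment before virtual-fragment pairing; the global budget is
  1000 draws per expected string. The whole tuple is redrawn on failure.
* **Boundary readings.** "Over 80%" keeps the exactly-80% read; the GC
  band is inclusive at both ends (with a 1e-9 float guard); windows
  shorter than half the window width are not evaluated on their own.
* **Degenerate inputs.** Empty input is a size error; inputs above the
  20 MiB job cap are refused; a pool whose constraints are unsatisfiable
  for the chosen pin fails with a diagnostic rather than spinning.

## Known limitations

* A homopolymer cap of 1 is unsatisfiable for any rule pair (one quarter
  of all dinucleotides are doubles); caps of 2-3 encode but with rising
  virtual-fragment overhead. The defaults (4 for oligos, 5 for long
  strings) are the practical regime.
* Highly repetitive inputs (long runs of one byte) produce many
  low-entropy fragments; they encode correctly but with more virtual
  fragments and thus lower net density. Pre-compression, deliberately
  out of scope, would remove the repetition at the source.
* Cluster representatives are selected, not polished: there is no
  consensus or indel realignment step, so recovery at very low depth
  leans entirely on RS and XOR.
* The homology screen scores candidates against a deterministic subsample
  of large pools; it is a mispriming heuristic, not a thermodynamic
  simulation.
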