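---
title: "Two-phase structure alignment: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase structure alignment: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdbalign)
```

`pdbalign` finds structural neighbours of a query protein chain in a
database of chains, using only backbone Cα coordinates.  This vignette is
the package's own account of the method: the two phases, every tunable
parameter with its default and rationale, the numerical conventions, the
synthetic fixtures the tests rely on, and the places where the design was
genuinely open and a choice had to be made.

## The similarity metrics

All comparisons reduce to per-residue distances $d_i$ between aligned Cα
pairs under a rigid-body superposition.  Two summaries are reported:

* **RMSD** $= \sqrt{\tfrac1N \sum_i d_i^2}$ over the $N$ aligned pairs —
  familiar, but dominated by the worst-fitting region and
  length-dependent for random pairs.
* **TM-score** $= \max \tfrac{1}{L} \sum_{i=1}^{N_{ali}}
  \bigl(1 + (d_i/d_0(L))^2\bigr)^{-1}$, where $L$ is the normalisation
  length, $N_{ali}$ the number of aligned pairs, and
  $d_0(L) = 1.24\sqrt[3]{L-15} - 1.8$ Å.  Each aligned pair contributes at
  most 1; unaligned residues of the normalising structure contribute 0, so
  the score rewards both accuracy and coverage.  Scores near 1 mean the
  same fold; random pairs score below about 0.2 regardless of length.

Two conventions need fixing because the defining formulas leave them open:

* **Normalisation length.**  We normalise by the template (shorter chain)
  length, consistently with the scoring matrix's $d_0(L_{min})$ below.
  Note that published benchmark numbers may normalise by the other chain;
  this is one reason external comparisons can shift by a few percent.
* **$d_0$ clamp.**  The cube-root formula goes nonpositive for
  $L \le 21$.  We clamp $d_0$ below at 0.5 Å — the standard convention — so
  the score stays defined for the short fragments and template parts the
  engine scores internally.

The max over superpositions is realised by `tm_score_optimal()`:
deterministic seeds (the Kabsch fit on all pairs, plus fits on contiguous
pair windows of half and quarter length anchored at the start, middle and
end of the alignment, the way fragment-based aligners seed their search),
each followed by iterative distance-cutoff refinement with the cutoff
schedule 8, 7, 6, 5, 4.5, 4, 3.5 Å and finally $d_0$; at every cutoff the
subset of pairs inside the cutoff is re-fit (Kabsch) and re-scored over
*all* pairs until the subset stabilises (at most 20 rounds).  The seeded
search exists because the plain all-pair fit can sit in the wrong basin
when only part of the alignment is superposable; on random 30-residue
decoy pairs the deterministic result matches a 2000-restart randomised
subset search to within $10^{-3}$ (see the geometry tests).  The result is
never below the plain Kabsch score.

Superpositions themselves come from the closed-form SVD (Kabsch) solution,
with the reflection case corrected so the rotation always has determinant
+1.  At least 3 non-collinear points are required.

## Phase 1: the secondary-structure filter

Each chain becomes a string over `{H, E, C, O}` (helix, strand, coil,
other), one character per residue.  Two sources are supported:

* **DSSP output files** (`read_dssp()` + `map_dssp_states()`).  The
  8-state DSSP alphabet collapses as H, G, I → `H`; E → `E`; T, S, B →
  `C`; blank/`-` → `O`.  Folding the 3₁₀ and π helix subtypes into `H`
  maximises the filter's sensitivity across helix subtypes.  This collapse
  is our choice — a different collapse would shift filter pass rates
  slightly.
* **Cα geometry** (`assign_sse_from_ca()`), so the tool runs with no
  external inputs.  A window is helical when $d(i,i{+}3) \approx 5.3$ Å
  and $d(i,i{+}4) \approx 6.4$ Å within 1.0 Å on 3 consecutive windows;
  strand when $d(i,i{+}2) \approx 6.7$ Å within 1.0 Å on 3 consecutive
  windows and the local trace is extended ($d(i,i{+}3) \ge 8$ Å, which
  separates extended geometry from helical winding).  Termini not covered
  by a complete window are `O`; everything else is `C`; chains under 5
  residues are all `O`.  The tolerances (1.0 Å) and the 3-window smoothing
  are calibration choices validated on the ideal generators below; the
  assignment is exactly invariant under rigid motion because it only uses
  distances.  When a DSSP file is supplied it takes precedence.

Strings are compared by longest-common-subsequence dynamic programming
(`lcs_matrix()`, $O(mn)$, borders zero, +1 on a match, max(up, left)
otherwise).  A pair **passes** the filter when
$S[m,n] > \min(m,n) \times 0.7$ — strictly, with the threshold kept as a
float.  The factor 0.7 is the published operating point balancing filter
selectivity against the risk of discarding genuine neighbours; it is
exposed as `filter_factor`.

The traceback (`lcs_traceback()`) recovers one optimal common
subsequence.  Optimal paths tie frequently; for determinism a match is
always taken diagonally, and on a mismatch the up move is taken only when
strictly better, otherwise left.  Only the LCS *length* feeds the filter
decision; the traceback is provided because the path is a useful
diagnostic, but phase 2 re-derives its own correspondence from geometry
and does not consume the phase-1 path.

## Phase 2: the residue-level aligner

The shorter chain is the **template** ($L_t$ residues; first argument on
ties), the longer the **constant** ($L_c$).  For a template part against a
constant window of equal length $W$, the scoring matrix is

$$M[i,j] = \max\{\, M[i{-}1,j] + g,\; M[i,j{-}1] + g,\;
M[i{-}1,j{-}1] + \tfrac{1}{1 + d_{ij}^2 / d_0(L_t)^2} \,\}$$

with first row and column zero and $d_{ij}$ the distance between template
residue $i$ (under the current superposition) and window residue $j$.
$d_0$ is always evaluated at the **full template length**, also when a
part is being scored, so part scores stay commensurate.  The traceback is
global from the bottom-right corner with tie-break diagonal > up > left.
The zero borders make leading gaps free, which is what gives the
alignment its local, "find the best offset" character.

* **Gap increment $g$.**  $g$ is *added* on every gap move, exactly as the
  recurrence is written; the default $3\times10^{-6}$ is the published
  setting for datasets of remote homologs, and 0.08 the published setting
  for structurally analogous pairs.  With $g$ near zero, gap moves are
  value-neutral against match terms of order 1; at 0.08 gaps actively
  compete with weak matches.  Both values are exposed (`gap_penalty`);
  whether the original intends addition or subtraction at 0.08 is not
  derivable from the recurrence as printed, so we keep the printed form.
* **Fragments.**  After the first traceback, maximal runs of ≥ 10 pairs
  consecutive in both chains (`collect_fragments()`) are pooled, a fresh
  Kabsch fit on their union re-seeds the matrix, and one more traceback is
  taken (`refine_alignment()`).  One refinement pass, not iteration to
  convergence: the procedure describes a single re-superposition, and in
  practice the second pass has already locked onto the superposable core.
  If no fragment survives, the first alignment stands.
* **Gapless threading** (`gapless_threading()`).  The template slides over
  all $L_c - L_t + 1$ windows from the N- to the C-terminus.  At each
  shift the *gapless identity correspondence* (template $i$ ↔ constant
  $s{+}i$) seeds the first Kabsch fit — the natural reading of
  "corresponding residues" in a threading frame.  The shift whose refined
  alignment scores the highest TM-score wins; ties go to the smaller
  shift.
* **Part groups.**  The template is split into $k \in \{1,2,3,5,8\}$
  contiguous parts of equal length (base size $\lfloor L_t/k \rfloor$, the
  first $L_t \bmod k$ parts one residue longer).  Parts thread in template
  order over *disjoint, ordered* constant regions: part $p$ only
  considers shifts at or after part $p{-}1$'s winning window end.  Without
  this constraint pooled alignments could cross; with it the pooled pair
  list is monotone by construction (a safety pass still drops any
  violator, keeping the earlier part's pairs).  A group is skipped when
  $k > L_t$ or when its parts would fall below 3 residues (no
  superposition is defined there); a later part whose window range is
  exhausted contributes no pairs.
* **Group scoring and selection.**  Each group's pooled pairs are scored
  by **one joint** `tm_score_optimal()` superposition normalised by
  $L_t$ — not a sum of per-part scores — because the TM-score of an
  alignment is only well defined under a single rigid transform.  The
  group with the highest TM-score is reported (`parts_used`), with RMSD
  computed over the pooled pairs under that same superposition.  The
  reported score is therefore monotone in the set of groups tried.

The joint-superposition rule has a consequence worth stating: splitting
the template helps when the constant contains the template's pieces *in
one rigid arrangement* that no contiguous window can cover (insertions,
embellishments between conserved halves).  It cannot reward pieces
related by *different* rigid motions — a joint fit can only satisfy one of
them — which is the flexible/hinge alignment problem, explicitly out of
scope.  The test fixture for the multi-part benefit
(`make_split_decoy()`) is built accordingly: both template halves are
embedded under a single shared transform, separated by a 15-residue coil
insertion, so a 2-part split provably wins over one part.

## Search

`search_one_vs_all()` runs phase 1 against every entry and phase 2 only on
survivors; `all_vs_all()` evaluates each unordered pair once
($n(n-1)/2$ pairs) and reports summary means over phase-2-completed pairs
(and a conservative all-pairs TM mean counting failures as 0, since a mean
over completed pairs alone overstates a database's similarity).  Hits rank
by TM-score descending, then identifier ascending — a total order, so
output is reproducible byte for byte.  The unit of parallel work is one
entry/pair; tasks are pure functions and results are assembled in input
order, so any worker count gives identical output (forked workers via
`parallel::mclapply`; serial fallback elsewhere).  Parallelism engages
above 8 tasks.  Phase-2 failures on degenerate entries are recorded as
missing metrics, never fatal.

## Synthetic fixtures: what they do and do not show

`make_chain()` generates idealised traces — helix (rise 1.5 Å, radius
2.3 Å, 100°/residue), strand (3.8 Å zig-zag with 6.7 Å $i{\to}i{+}2$
spacing), self-avoiding coil (3.8 Å steps, non-bonded pairs kept beyond
3.5 Å by rejection sampling), and mixed (≈ 40/30/30 helix/coil/strand
segments joined at random orientations) — with optional Gaussian
coordinate noise and a known rigid motion, deterministically per seed.
Ground-truth secondary structure accompanies every chain.
`make_decoy_with_embedded_template()` plants an exact rigid copy of a
template at a known offset inside a coil decoy;
`make_split_decoy()` plants the two halves around an insertion as
described above.

These fixtures give planted answers — offsets, transforms, labels — that
the algorithms must recover exactly at zero noise, and they exercise every
code path.  What they do *not* emulate: real loop geometry and
Ramachandran statistics, β-sheet pairing between strands, domain motions,
missing residues, or the length and fold distribution of a real database.
Passing these tests shows the machinery is correct and deterministic, not
that benchmark-level accuracy on curated alignment sets is reproduced;
published benchmark numbers additionally depend on the exact DSSP
collapse and normalisation conventions noted above, and on datasets that
must be fetched separately.

## Problem sizes and numerical notes

The test suite and the acceptance script run at deliberately modest
scale, chosen so a complete run exercises every claim in seconds to
minutes on one core: database screening over 200 chains of 20–45 residues
(19,900 pairs, filter only), LCS oracles at string lengths ≤ 12 (where
exhaustive enumeration is feasible), threading recovery with 30-residue
templates in 70-residue decoys over 20 seeds, and brute-force path
enumeration at template lengths ≤ 6.  The algorithms themselves have no
size-dependent switches; protein-scale chains (≤ ~1100 residues) keep the
full LCS matrix comfortably in memory, which is why the simple quadratic
fill is retained rather than a linear-space variant.

Degenerate inputs are handled explicitly: empty strings score LCS 0;
chains under 5 residues refuse residue-level alignment; under 3 points no
superposition is attempted; an all-zero distance set gives RMSD 0 and
TM-score 1.  Floating-point tracebacks compare against matrix entries
computed from the same stored match terms, so move decisions are exact,
not tolerance-based.

## Known limitations

* Sequential alignments only: no hinge/flexible mode, no
  sequence-order-independent mode.
* The geometric SSE assigner is a deliberately simple distance-signature
  classifier; on real structures it will disagree with DSSP at element
  boundaries, shifting phase-1 pass rates.
* The multi-part combiner's ordered-disjoint-window constraint forbids
  template parts matching out of order (circular permutations).
* TM-score maximisation is a seeded local search; pathological pair sets
  could in principle hide a better superposition from every seed.
* mmCIF input is not parsed; convert to PDB first.
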