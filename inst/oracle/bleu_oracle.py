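#!/usr/bin/env python3
"""Independent corpus BLEU implementation used as a cross-check in tests.

Reads a JSON file: a list of {"refs": [...], "hyps": [...]} corpora.
Writes a JSON list of BLEU scores (one per corpus) to stdout.

Implements clipped n-gram precision (N = 4) pooled over the corpus, a
brevity penalty exp(1 - r/c) for c <= r, uniform weights, and no smoothing;
orders with no hypothesis n-grams at all are excluded from the geometric
mean (degenerate short corpora).
"""
import json
import math
import sys
from collections import Counter


def tokens(s):
    return s.split()


def ngrams(toks, n):
    return Counter(tuple(toks[i:i + n]) for i in range(len(toks) - n + 1))


def corpus_bleu(refs, hyps, max_n=4):
    assert len(refs) == len(hyps)
    r = sum(len(tokens(x)) for x in refs)
    c = sum(len(tokens(x)) for x in hyps)
    match = [0] * max_n
    total = [0] * max_n
    for ref, hyp in zip(refs, hyps):
        rt, ht = tokens(ref), tokens(hyp)
        for n in range(1, max_n + 1):
            hc = ngrams(ht, n)
            if not hc:
                continue
            rc = ngrams(rt, n)
            match[n - 1] += sum(min(cnt, rc.get(g, 0)) for g, cnt in hc.items())
            total[n - 1] += sum(hc.values())
    orders = [i for i in range(max_n) if total[i] > 0]
    if not orders or any(match[i] == 0 for i in orders):
        return 0.0
    if c == 0:
        return 0.0
    bp = 1.0 if c > r else math.exp(1.0 - r / c)
    log_p = sum(math.log(match[i] / total[i]) for i in orders) / len(orders)
    return bp * math.exp(log_p)


def main():
    with open(sys.argv[1], encoding="utf-8") as fh:
        corpora = json.load(fh)
    out = [corpus_bleu(c["refs"], c["hyps"]) for c in corpora]
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
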