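"""Molecule encoding backend.

Reads SMILES (one per line) and emits, per molecule, a parse flag, the
canonical SMILES, and optionally a 758-position fingerprint vector laid
out as three concatenated blocks:

  positions   1-167  MACCS structural keys (position 1 reserved, always 0)
  positions 168-246  E-State atom-type counts (79 types, fixed order)
  positions 247-758  functional-group substructure bits (512 slots, SMARTS
                     patterns supplied via --patterns; unassigned slots 0)

Unparseable SMILES yield ok=0 and an all-zero vector; the caller decides
how to handle them.
"""

import argparse
import csv
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import MACCSkeys
from rdkit.Chem.EState import Fingerprinter as EStateFP

RDLogger.DisableLog("rdApp.*")

N_MACCS = 167
N_ESTATE = 79
N_FG = 512


def load_patterns(path):
    """Return list of (slot_index_0based, compiled_pattern)."""
    out = []
    with open(path) as fh:
        rd = csv.reader(fh, delimiter="\t")
        for row in rd:
            if not row or row[0].startswith("#"):
                continue
            slot = int(row[0])
            patt = Chem.MolFromSmarts(row[2])
            if patt is None:
                raise ValueError("bad SMARTS in slot %d: %s" % (slot, row[2]))
            if not 1 <= slot <= N_FG:
                raise ValueError("slot out of range: %d" % slot)
            out.append((slot - 1, patt))
    return out


def encode(mol, patterns):
    maccs = MACCSkeys.GenMACCSKeys(mol)  # 167 bits, bit 0 unused
    vec = [0] * (N_MACCS + N_ESTATE + N_FG)
    for b in maccs.GetOnBits():
        vec[b] = 1
    counts, _ = EStateFP.FingerprintMol(mol)  # 79 atom-type counts
    for i in range(N_ESTATE):
        vec[N_MACCS + i] = int(counts[i])
    for slot, patt in patterns:
        if mol.HasSubstructMatch(patt):
            vec[N_MACCS + N_ESTATE + slot] = 1
    return vec


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--smiles", required=True)
    ap.add_argument("--out", required=True)
    ap.add_argument("--patterns")
    ap.add_argument("--canon-only", action="store_true")
    args = ap.parse_args()

    patterns = []
    if not args.canon_only:
        if not args.patterns:
            sys.exit("--patterns required unless --canon-only")
        patterns = load_patterns(args.patterns)

    nfail = 0
    with open(args.smiles) as fin, open(args.out, "w", newline="") as fout:
        wr = csv.writer(fout)
        for line in fin:
            smi = line.strip()
            mol = Chem.MolFromSmiles(smi) if smi else None
            if mol is None:
                nfail += 1
                row = [0, ""]
                if not args.canon_only:
                    row += [0] * (N_MACCS + N_ESTATE + N_FG)
            else:
                row = [1, Chem.MolToSmiles(mol)]
                if not args.canon_only:
                    row += encode(mol, patterns)
            wr.writerow(row)
    print("failed=%d" % nfail, file=sys.stderr)


if __name__ == "__main__":
    main()
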