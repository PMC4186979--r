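"""JSON bridge between the R package and RDKit.

Invoked as:  python chem_bridge.py <request.json> <response.json>

The request is {"task": <name>, ...task-specific fields...}; the response is a
JSON object.  Errors are reported as {"error": <message>} with exit code 0 so
the R side can raise a proper R condition.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, MACCSkeys, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def _parse_all(smiles_list):
    """Parse SMILES; returns (mols, ok flags, canonical SMILES or None)."""
    mols, ok, canon = [], [], []
    for smi in smiles_list:
        m = Chem.MolFromSmiles(smi) if smi is not None else None
        mols.append(m)
        ok.append(m is not None)
        canon.append(Chem.MolToSmiles(m) if m is not None else None)
    return mols, ok, canon


def task_parse_smiles(req):
    _, ok, canon = _parse_all(req["smiles"])
    return {"ok": ok, "canonical": canon}


def task_match_smarts(req):
    mols, ok, _ = _parse_all(req["smiles"])
    if not all(ok):
        bad = [i + 1 for i, o in enumerate(ok) if not o]
        return {"error": "unparseable structure at compound index(es): %s"
                % ", ".join(map(str, bad))}
    patterns = []
    for pat in req["smarts"]:
        q = Chem.MolFromSmarts(pat)
        if q is None:
            return {"error": "unparseable SMARTS pattern: %s" % pat}
        patterns.append(q)
    matrix = [[1 if m.HasSubstructMatch(q) else 0 for q in patterns]
              for m in mols]
    return {"matrix": matrix}


DESCRIPTORS = {
    "mw": lambda m: Descriptors.MolWt(m),
    "logp": lambda m: Crippen.MolLogP(m),
    "tpsa": lambda m: rdMolDescriptors.CalcTPSA(m),
    "nbonds": lambda m: m.GetNumBonds(),  # heavy-atom bonds (implicit H free)
    "mr": lambda m: Crippen.MolMR(m),
}


def task_descriptors(req):
    names = req["names"]
    unknown = [n for n in names if n not in DESCRIPTORS]
    if unknown:
        return {"error": "unknown descriptor(s): %s; available: %s"
                % (", ".join(unknown), ", ".join(sorted(DESCRIPTORS)))}
    mols, ok, _ = _parse_all(req["smiles"])
    if not all(ok):
        bad = [i + 1 for i, o in enumerate(ok) if not o]
        return {"error": "unparseable structure at compound index(es): %s"
                % ", ".join(map(str, bad))}
    return {"values": {n: [DESCRIPTORS[n](m) for m in mols] for n in names}}


def task_maccs_smarts(req):
    # The 166-key MACCS list as shipped with RDKit; three keys (1, 125, 166)
    # are not expressible as a single SMARTS and are returned as None.
    out = []
    for key in range(1, 167):
        smarts, _count = MACCSkeys.smartsPatts[key]
        out.append(None if smarts == "?" else smarts)
    return {"smarts": out}


def task_smiles_to_molblock(req):
    mols, ok, _ = _parse_all(req["smiles"])
    if not all(ok):
        bad = [i + 1 for i, o in enumerate(ok) if not o]
        return {"error": "unparseable structure at compound index(es): %s"
                % ", ".join(map(str, bad))}
    names = req.get("names") or [""] * len(mols)
    blocks = []
    for m, name in zip(mols, names):
        m = Chem.Mol(m)
        m.SetProp("_Name", str(name) if name is not None else "")
        blocks.append(Chem.MolToMolBlock(m, kekulize=True))
    return {"molblocks": blocks}


def task_molblock_to_smiles(req):
    smiles, ok = [], []
    for block in req["molblocks"]:
        m = Chem.MolFromMolBlock(block, sanitize=True)
        ok.append(m is not None)
        smiles.append(Chem.MolToSmiles(m) if m is not None else None)
    return {"smiles": smiles, "ok": ok}


TASKS = {
    "parse_smiles": task_parse_smiles,
    "match_smarts": task_match_smarts,
    "descriptors": task_descriptors,
    "maccs_smarts": task_maccs_smarts,
    "smiles_to_molblock": task_smiles_to_molblock,
    "molblock_to_smiles": task_molblock_to_smiles,
}


def main():
    req_path, resp_path = sys.argv[1], sys.argv[2]
    with open(req_path) as fh:
        req = json.load(fh)
    task = req.get("task")
    if task not in TASKS:
        resp = {"error": "unknown bridge task: %r" % task}
    else:
        try:
            resp = TASKS[task](req)
        except Exception as exc:  # surfaced as an R error
            resp = {"error": "%s: %s" % (type(exc).__name__, exc)}
    with open(resp_path, "w") as fh:
        json.dump(resp, fh)


if __name__ == "__main__":
    main()
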