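# Quinone scaffold library bundled with quinoscreen.
# One SMILES per line, optional whitespace-separated name.
O=C1C=CC(=O)C=C1	1,4-benzoquinone
O=C1C=CC=CC1=O	1,2-benzoquinone
O=C1C=CC(=O)c2ccccc12	1,4-naphthoquinone
O=C1C=Cc2ccccc2C1=O	1,2-naphthoquinone
O=C1c2ccccc2C(=O)c2ccccc21	9,10-anthraquinone
O=C1C=CC(=O)c2cc3ccccc3cc12	1,4-anthraquinone
CC1=CC(=O)C=CC1=O	2-methyl-1,4-benzoquinone
CCC1=CC(=O)C=CC1=O	2-ethyl-1,4-benzoquinone
CC1=C(C)C(=O)C=CC1=O	2,3-dimethyl-1,4-benzoquinone
CC1=CC(=O)C(C)=CC1=O	2,5-dimethyl-1,4-benzoquinone
CC1=CC(=O)C=C(C)C1=O	2,6-dimethyl-1,4-benzoquinone
COC1=CC(=O)C=CC1=O	2-methoxy-1,4-benzoquinone
CC1=CC(=O)c2ccccc2C1=O	menadione
CC1=C(C)C(=O)c2ccccc2C1=O	2,3-dimethyl-1,4-naphthoquinone
OC1=CC(=O)c2ccccc2C1=O	lawsone
O=C1C=CC(=O)c2ncccc12	quinoline-5,8-dione
O=C1c2ccccc2-c2ccccc2C1=O	phenanthrene-9,10-dione
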