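>AtSBP01_synthetic
REFYHYCPIFVCVTTREPVNWNSCLCCANCSGSFRDSHPPKLCNCHNGIQTPKIPIVQAHHFEHIWNICSCSHTEA
>AtSBP02_synthetic
KKFFHYCCIFVCVTHREPINWNVCLCCANCIGSFARSKPPYLCNDHNGIRTPTISIQQAHHFEHINNICSYSHTES
>AtSBP03_synthetic
RKFCHYCPIFVCVTHREPMNWNVCLCCANCSGSFARMHPPKLQSAHNGPQQPTISIVQAHHFEHIWNICSVEHTEA
>AtSBP04_synthetic
RKACHYCPIFVCVTHREPVNWNVCWCCAN---SFARYPPPKLCNADNGIQTPTISIVDAHHFEHIWNICSCSHTEA
>AtSBP05_synthetic
RKFCHYCPIFVCVTHREPVNFNVCLCCANCSGSFARSHPPKLCTAHHGIQTPVISIVQAHHPEHIWNICSCSITEA
>AtSBP06_synthetic
RKCCMYCPIFVCLTHHEPDMWNVCLCCAQCSGSFARSHPPKLCNIHNGIQNPTISIVQAHHFELIWNPCSCSHTEA
>AtSBP07_synthetic
RQFAHYCPIFVCHTHREPVNSNNCLCCAYNSGSFARSHPSKLHNAHNGIQTPTISIHQCHLFEHIWNICSCSMTEA
>AtSBP08_synthetic
RKFCHYCPIFVCVTHREPVNWNVWLQCANCSVSFARSHPPKLCNAHWGIQTPTISIVQAHLFEHI--ICSCSHTEA
>AtSBP09_synthetic
RKFCHYCPIFVCVTHREPVNWNVCLCVAQASRNFARSHPPKLYNAHNGIQHVTISIVQLHHFEHIWNIWSREHTEG
>AtSBP10_synthetic
RKFCHYCPIFSCVTLREPVNWDVCLCCANCSGVFAHQHPPKLCNWHNGIETPTQIIVQAHHHEHHWNICSCSHTEA
>AtSBP11_synthetic
HKACEYCPRFVCVTHREFVNWNVCLCCANCSGPLARSHPPKLCNAHNGIQTPTISIVQAHHFEHIWNICSCSHTEA
>AtSBP12_synthetic
RKFCHCKPIFVCVTHREPVNWNVCLCCANCSGSFARSHPPKLCNAHNGIQTPTISIV--GHPEDIWNICSCSHTEA
>AtSBP13_synthetic
EKFCHPCPTFVCVTHRTPVNSNVCLCCANCSGSFIRSHPGKLCNAHNWQKTPTISIVQAHAFEHIWNICSCSHTQA
>AtSBP14_synthetic
HKFCHYCPIFVMVTHSEPVWWNVCLCCAKCSGSFARSHPPRLCNAHNGVQTPTMSFKQAHHFEHIWNICSCSDTEA
>AtSBP15_synthetic
RKFCHYCPIFVCVQHREPVNWNVCLGCANGSGSFCRCAPPKLCNAHNGIQTITISIVQAHTFSHIWNICSCSHTEA
>AtSBP16_synthetic
RKFCHQCPIFVAVTHREPVNWN--LCCAKCSGSFARSHPPKLCNAHNGIQTPTISIVQAHHREHTWNICSCQGTEA
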