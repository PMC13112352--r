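>sv01
EKEKEKEKEKEKEKEKEKEKEKEKEKEKEKEKEKEKEKEKEKEKEKEKEK
>sv02
KEKEKEKEEKEKKEKEKEEKEKKEKEKEKEKEKEEKEKEKKEKEKEKEKE
>sv03
KEKEKEEKKKEEKEKEKEEKKEEKEKEKEKKEKEKEEKKEKEKEEKKKEE
>sv04
KKEEKEKEKEEKEKEKKEEEKKEKEEKEKKKEKEEKKEEKKKEEKEEKKE
>sv05
KEEKKEEEKKKKEEEEEKEKKKEKEKEKEKKEKEEKEKEKKEKEKEEKEK
>sv06
KEKKEEKEEKEEKKKEKKEEKEEEEKEKKKKEKEEKKEKEEEKKEEKEKK
>sv07
KEEEKKEEEKKEKEKEKKEEKEKKKEEKEKKKEEEEEKEKKKKKEKEKEE
>sv08
EKKEEEKEEEKEKKKKEKKEEKEEKEKEKEKEEEKKKKKKEEEKKEEEKK
>sv09
KEEEEEEKKEEKKKKEKEKKEKKEEEKKKEEKEKEKKEKKEKKEEKEEKE
>sv10
EEEKKKKKEKKEEKKEEEEKKEKEEKEEEEKEEKKEKKKKKKEEKEEKKE
>sv11
EEEKKEKKEEEEEEKKEKKEKEEKKKKEKKKKEEKEEEEKEKKKKEEKKE
>sv12
KKKEKKKEKEEEKKEKKEEEEEEEKEEKEEKKEEKKEKEKKKEKEKKEKE
>sv13
EKEEKEEEEKKKKKEEEEEKEKEKEEKKKEKKKEKKKKKEKKEKEEEEEK
>sv14
KKEEKKEKKKEEKKKKEEKEKKEKEEEEEEEKEEEEKKEEEKKEKKEKKK
>sv15
EEEEEKEEKEEKKKEKEEKEKKEKEEEKKKKKKKKEKKKEEKEEEEEKKK
>sv16
EEEEEKEEEEKEKKKEKKEEEKEEKKKKEKEEKKKEKEEKKEKKEKEKKK
>sv17
KEKKKKKKKEKEKKKEEEEEKEEEEKEEKEKKKEKKKKKKEEKEEEEEEE
>sv18
KKKEKKEKEEKEKKKKKKKEEKKEKEEKEKKEEKEKEEEKEEEEEEEKKE
>sv19
KKEKEKKKKEEEEEEEEEEEKEKEEEKEEKEKKEEEKKEKKKKKKKKEKK
>sv20
KKKKEEKKKKKKEKKEKKKEKEEEKEKEKEKEKEEKEEEKEEKKEEEEEE
>sv21
EEEEEKEKEEEEEKKEEEKEEKEKKEEKKEKKEEKKEKKEKKKEKKKKKK
>sv22
EEEEEEEKEEEKKEEEKEEEEEEKKKKKKKKEKKKEKEKKKKKKEKEKKE
>sv23
EEEEEEEEKEKEEKEKEEEEEEKEKKKEKEKEKKKKEKKEKKKEKKKKKK
>sv24
KKKKKKKKKEKKKKKKKKEEKEKEEEEEEEEKEKEKEEEEEKEEEEEEKK
>sv25
KKKKKKKKKKKKKEKKEKEEKEKKEKEKEEKEEKEEEKKEEEEEEEEEEE
>sv26
EEEEEEEEEEEEEEEKKKEKEKEEEEEKKKEKKKEKKKEKKKKKKKKKKK
>sv27
KKEKKKKKKKKKKKKKKEKEKKKEEKEKKKEEKEEEEEEEEEEEEEEEEE
>sv28
EEEEEEEEEEEEEKEEEEEEEKEKKEKEKKEEKKKKKKKKKKKKKKKKKK
>sv29
KKKKKKKKKKKKKKKKKKKEKKKKEEEKEEEKEEEEEEEEEEEEEEEEEE
>sv30
EEEEEEEEEEEEEEEEEEEEEEEEEKKKKKKKKKKKKKKKKKKKKKKKKK
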